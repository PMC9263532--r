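# Lexicon for the rule-based bilateral-infiltrate classifier.
# A report is positive when a non-negated infiltrate term and a non-negated
# laterality term occur in the same sentence within `pair_window` tokens.
# Multi-word entries are matched as token phrases. Negation cues negate up to
# `scope` following tokens, stopping early at a terminator token or sentence
# boundary. Uncertainty cues carry positive polarity (a hedged finding still
# screens positive) and are only recorded.
target:
  infiltrate_terms:
    - infiltrate
    - infiltrates
    - infiltration
    - opacity
    - opacities
    - consolidation
    - consolidations
    - airspace disease
    - air space disease
    - ground glass opacities
  laterality_terms:
    - bilateral
    - bilaterally
    - both lungs
    - both lung fields
    - both lower lobes
    - right and left
  pair_window: 6
negation:
  cues:
    - {cue: "no", scope: 5}
    - {cue: "not", scope: 5}
    - {cue: "without", scope: 5}
    - {cue: "no evidence of", scope: 5}
    - {cue: "without evidence of", scope: 5}
    - {cue: "free of", scope: 5}
    - {cue: "clear of", scope: 5}
    - {cue: "absence of", scope: 5}
    - {cue: "negative for", scope: 5}
    - {cue: "resolution of", scope: 5}
    - {cue: "clearing of", scope: 5}
  terminators:
    - but
    - however
    - although
    - though
    - except
    - aside
uncertainty:
  cues:
    - possible
    - probable
    - questionable
    - cannot exclude
    - cannot rule out
    - may represent
    - concerning for
    - suspicious for
  polarity: positive
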