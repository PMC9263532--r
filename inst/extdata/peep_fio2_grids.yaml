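# Allowed PEEP (cmH2O) per FiO2 level for the oxygenation protocol.
# Two strategies: low_peep (lower-PEEP/higher-FiO2 titration table) and
# high_peep (higher-PEEP/lower-FiO2 table), both from the public ARDSNet
# tables. Lookup rule: nearest grid FiO2 level not above the charted FiO2;
# a charted PEEP within `peep_tolerance` cmH2O of any allowed value is
# adherent.
low_peep:
  - {fio2: 0.21, peep: [5]}
  - {fio2: 0.30, peep: [5]}
  - {fio2: 0.40, peep: [5, 8]}
  - {fio2: 0.50, peep: [8, 10]}
  - {fio2: 0.60, peep: [10]}
  - {fio2: 0.70, peep: [10, 12, 14]}
  - {fio2: 0.80, peep: [14]}
  - {fio2: 0.90, peep: [14, 16, 18]}
  - {fio2: 1.00, peep: [18, 20, 22, 24]}
high_peep:
  - {fio2: 0.21, peep: [5, 8, 10, 12, 14]}
  - {fio2: 0.30, peep: [5, 8, 10, 12, 14]}
  - {fio2: 0.40, peep: [14, 16]}
  - {fio2: 0.50, peep: [16, 18, 20]}
  - {fio2: 0.60, peep: [20]}
  - {fio2: 0.70, peep: [20]}
  - {fio2: 0.80, peep: [20, 22]}
  - {fio2: 0.90, peep: [22]}
  - {fio2: 1.00, peep: [22, 24]}
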