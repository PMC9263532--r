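id	label	text
pos01	positive	Diffuse bilateral infiltrates consistent with pulmonary edema.
pos02	positive	Endotracheal tube in standard position. Patchy bilateral opacities compatible with multifocal pneumonia.
pos03	positive	Interval worsening of airspace disease bilaterally. Heart size stable.
pos04	positive	There are bilateral infiltrates with perihilar distribution. Lines unchanged.
pos05	positive	Persistent bilateral opacities. No pneumothorax.
pos06	positive	Extensive consolidations in both lungs, worse at the bases.
pos07	positive	Confluent airspace disease involving both lung fields.
pos08	positive	Bilateral ground glass opacities, new from prior study.
pos09	positive	Worsening infiltrates bilaterally since yesterday.
pos10	positive	Dense consolidation in the right and left lower lobes.
pos11	positive	Diffuse opacities in both lower lobes consistent with ARDS.
pos12	positive	Nasogastric tube below the diaphragm. Bilateral patchy infiltrates again noted.
pos13	positive	Low lung volumes. Hazy opacities bilaterally, increased from prior.
pos14	positive	Stable support devices. Persistent bilateral airspace disease.
pos15	positive	Bilateral perihilar infiltrates suggesting edema, slightly worse.
pos16	positive	New patchy infiltration bilaterally, compatible with aspiration.
pos17	positive	No fracture identified, but bilateral infiltrates are present.
pos18	positive	Cardiomegaly unchanged. Increasing bilateral opacities at the bases.
unc01	positive	Possible bilateral infiltrates; cannot exclude early ARDS.
unc02	positive	Questionable patchy bilateral opacities, may represent pulmonary edema.
unc03	positive	Hazy airspace disease bilaterally, concerning for multifocal pneumonia.
unc04	positive	Findings suspicious for bilateral infiltrates; clinical correlation advised.
unc05	positive	Probable bilateral consolidations, incompletely evaluated on portable film.
unc06	positive	Possible diffuse opacities bilaterally; recommend repeat radiograph.
unc07	positive	Subtle bilateral infiltrates, cannot rule out developing edema.
unc08	positive	Ill-defined opacities in both lungs, may represent atelectasis versus pneumonia.
unc09	positive	Questionable airspace disease in both lower lobes.
unc10	positive	Probable perihilar infiltrates bilaterally, concerning for fluid overload.
unc11	positive	Possible consolidations in the right and left bases.
unc12	positive	Vague bilateral opacities suspicious for early airspace process.
unc13	positive	Hazy bilateral infiltration, may represent interstitial edema.
unc14	positive	Equivocal bilateral airspace disease; comparison limited by rotation.
unc15	positive	Findings concerning for bilateral ground glass opacities.
unc16	positive	Probable mild bilateral infiltrates, new since admission.
unc17	positive	Possible patchy consolidation bilaterally, cannot exclude infection.
unc18	positive	Suspected bilateral opacities; correlate with oxygenation.
neg01	negative	No focal infiltrate or consolidation. Lungs otherwise well aerated.
neg02	negative	Lines in standard position. No evidence of airspace disease.
neg03	negative	No infiltrate identified. Small left pleural effusion, stable.
neg04	negative	Interval clearing of consolidation. Heart size within normal limits.
neg05	negative	Negative for infiltrate. Degenerative changes of the spine.
neg06	negative	No focal infiltrate; lungs clear bilaterally.
neg07	negative	Without evidence of consolidation or effusion.
neg08	negative	No new opacities. Support devices unchanged.
neg09	negative	Resolution of opacities since the prior examination.
neg10	negative	No airspace disease. Mild cardiomegaly.
neg11	negative	Lungs free of infiltrate. No pneumothorax or effusion.
neg12	negative	No focal consolidation, and the costophrenic angles are sharp.
neg13	negative	Clearing of infiltrates compared with yesterday. Tubes unchanged.
neg14	negative	No evidence of infiltration or pleural fluid.
neg15	negative	Absence of consolidation. Central venous catheter tip in the cavoatrial junction.
neg16	negative	No opacities seen. Bony thorax intact bilaterally.
neg17	negative	Negative for airspace disease. Stable mediastinal contour.
neg18	negative	No consolidation identified; both lungs remain expanded.
clr01	negative	Lungs are clear. Heart size and mediastinum are normal.
clr02	negative	Clear lungs without pleural effusion. Tubes and lines unchanged.
clr03	negative	No acute cardiopulmonary abnormality.
clr04	negative	Heart size normal. Costophrenic angles are sharp.
clr05	negative	Both lungs are well aerated. Endotracheal tube 4 cm above the carina.
clr06	negative	Stable chest radiograph. Support devices in standard position.
clr07	negative	Normal cardiac silhouette. The lungs remain clear bilaterally.
clr08	negative	Unremarkable portable chest examination.
clr09	negative	Lungs clear. Degenerative changes of the thoracic spine.
clr10	negative	Well expanded and clear lungs. Sternotomy wires intact.
clr11	negative	Clear lung fields with normal pulmonary vascularity.
clr12	negative	No effusion or pneumothorax. Cardiac size at the upper limits of normal.
clr13	negative	The examination is unchanged from prior. Lungs grossly clear.
clr14	negative	Midline sternotomy. Lungs clear, pleural spaces dry.
clr15	negative	Tracheostomy tube in place. Lungs remain clear.
clr16	negative	Mild pulmonary vascular congestion only.
clr17	negative	Right basilar atelectasis. Otherwise clear lungs.
clr18	negative	Low lung volumes without focal abnormality.
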