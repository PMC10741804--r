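# Planning dose constraints, 7095 cGy / 33 fx head-and-neck plan.
# Laterality-free protocol rows (cochlea, brachial plexus) are expanded
# to both sides.
site: head_and_neck
prescription_cGy: 7095
constraints:
  - {structure: PTV, statistic: Dmin, direction: at-least, limit: 6953}
  - {structure: PTV, statistic: Dmax, direction: at-most, limit: 7591}
  - {structure: Brain, statistic: V6000cGy, direction: at-most, limit: 3}
  - {structure: Brainstem, statistic: Dmax, direction: at-most, limit: 5000}
  - {structure: Left Cochlea, statistic: Dmean, direction: at-most, limit: 4500}
  - {structure: Right Cochlea, statistic: Dmean, direction: at-most, limit: 4500}
  - {structure: Spinal Cord, statistic: Dmax, direction: at-most, limit: 3600}
  - {structure: PRV_Spinal Cord, statistic: Dmax, direction: at-most, limit: 4000}
  - {structure: Oral Cavity, statistic: Dmean, direction: at-most, limit: 3000}
  - {structure: Oral Cavity, statistic: V3000cGy, direction: at-most, limit: 73}
  - {structure: Oral Cavity, statistic: V4000cGy, direction: at-most, limit: 20}
  - {structure: Ipsilateral Parotid, statistic: Dmean, direction: at-most, limit: 2600}
  - {structure: Contralateral Parotid, statistic: Dmean, direction: at-most, limit: 2000}
  - {structure: Ipsilateral Submandibular Gland, statistic: Dmean, direction: at-most, limit: 5000}
  - {structure: Contralateral Submandibular Gland, statistic: Dmean, direction: at-most, limit: 3900}
  - {structure: Mandible, statistic: V5000cGy, direction: at-most, limit: 31}
  - {structure: Arytenoid Cartilage, statistic: V5000cGy, direction: at-most, limit: 50}
  - {structure: Constrictor Muscle, statistic: V5000cGy, direction: at-most, limit: 70}
  - {structure: Constrictor Muscle-PTV, statistic: Dmean, direction: at-most, limit: 5000}
  - {structure: Constrictor Muscle-PTV, statistic: V5000cGy, direction: at-most, limit: 31}
  - {structure: Constrictor Muscle-PTV, statistic: V5000cGycc, direction: at-most, limit: 31}
  - {structure: Thyroid, statistic: Dmean, direction: at-most, limit: 4500}
  - {structure: Thyroid, statistic: V4000cGy, direction: at-most, limit: 50}
  - {structure: Thyroid, statistic: V3000cGy, direction: at-most, limit: 60}
  - {structure: Left Brachial Plexus, statistic: V6000cGycc, direction: at-most, limit: 0.1}
  - {structure: Right Brachial Plexus, statistic: V6000cGycc, direction: at-most, limit: 0.1}
  - {structure: Esophagus, statistic: V3500cGy, direction: at-most, limit: 50}
  - {structure: Esophagus, statistic: V5000cGy, direction: at-most, limit: 40}
  - {structure: Esophagus, statistic: V7000cGy, direction: at-most, limit: 20}
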