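alias,canonical
PTV,PTV
CTV,CTV
Prostate,CTV
Rectum,Rectum
Bladder,Bladder
Anal Canal,Anal Canal
AnalCanal,Anal Canal
Canal_Anale,Anal Canal
Left Femur,Left Femur
Femur Left,Left Femur
Femur_L,Left Femur
FemoralHead_L,Left Femur
Right Femur,Right Femur
Femur Right,Right Femur
Femur_R,Right Femur
FemoralHead_R,Right Femur
Brain,Brain
Brainstem,Brainstem
BrainStem,Brainstem
Chiasm,Chiasm
OpticChiasm,Chiasm
Contralateral Cochlea,Right Cochlea
Cochlea_Contralateral,Right Cochlea
Cochlea_C,Right Cochlea
Right Cochlea,Right Cochlea
Ipsilateral Cochlea,Left Cochlea
Cochlea_Ipsilateral,Left Cochlea
Cochlea_I,Left Cochlea
Left Cochlea,Left Cochlea
Esophagus,Esophagus
Left Eye,Left Eye
Eye_L,Left Eye
Right Eye,Right Eye
Eye_R,Right Eye
Larynx,Larynx
Left Lens,Left Lens
Lens_L,Left Lens
Right Lens,Right Lens
Lens_R,Right Lens
Mandible,Mandible
Left Optic Nerve,Left Optic Nerve
OpticNerve_L,Left Optic Nerve
Right Optic Nerve,Right Optic Nerve
OpticNerve_R,Right Optic Nerve
Oral Cavity,Oral Cavity
OralCavity,Oral Cavity
Contralateral Parotid,Right Parotid
Parotid_Contralateral,Right Parotid
Parotid_C,Right Parotid
Right Parotid,Right Parotid
Ipsilateral Parotid,Left Parotid
Parotid_Ipsilateral,Left Parotid
Parotid_Ipsilatateral,Left Parotid
Parotid_H,Left Parotid
Left Parotid,Left Parotid
Pharynx Constrictor Muscle,Pharynx Constrictor Muscle
PharynxConst,Pharynx Constrictor Muscle
Constrictor Muscle,Pharynx Constrictor Muscle
Pituitary,Pituitary
Spinal Cord,Spinal Cord
SpinalCord,Spinal Cord
PRV_Spinal Cord,PRV Spinal Cord
PRV_SpinalCord,PRV Spinal Cord
Contralateral Submandibular,Right Submandibular
Contralateral Submandibular Gland,Right Submandibular
Submandibular_Co,Right Submandibular
Right Submandibular,Right Submandibular
Ipsilateral Submandibular,Left Submandibular
Ipsilateral Submandibular Gland,Left Submandibular
Submandibular_Ho,Left Submandibular
Left Submandibular,Left Submandibular
Thyroid,Thyroid
Trachea,Trachea
Contralateral Brachial Plexus,Right Brachial Plexus
BrachialPlexus_C,Right Brachial Plexus
Right Brachial Plexus,Right Brachial Plexus
Ipsilateral Brachial Plexus,Left Brachial Plexus
BrachialPlexus_O,Left Brachial Plexus
Left Brachial Plexus,Left Brachial Plexus
Arytenoid Cartilage,Arytenoid Cartilage
Constrictor Muscle-PTV,Constrictor Muscle-PTV
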