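symptoms:
- label: Developmental speech, language disorder
  likelihood: high
  category: bulbar
  subgroup: Speech
  patterns:
  - '315.39'
- label: Speech and language deficits
  likelihood: high
  category: bulbar
  subgroup: Speech
  patterns:
  - 438.1X
  - '784.3'
  - 784.4X
  - 784.5X
- label: Dysphagia
  likelihood: high
  category: bulbar
  subgroup: Speech
  patterns:
  - '787.2'
  - '438.82'
- label: Disturbance, salivary secretion
  likelihood: high
  category: bulbar
  subgroup: Swallowing
  patterns:
  - '527.7'
- label: Salivary gland disorder
  likelihood: high
  category: bulbar
  subgroup: Swallowing
  patterns:
  - '527.8'
- label: Pain, throat
  likelihood: high
  category: bulbar
  subgroup: Swallowing
  patterns:
  - '784.1'
- label: Atrophy, muscular disuse
  likelihood: high
  category: limb
  subgroup: Muscle strength
  patterns:
  - '728.2'
- label: Muscle weakness (generalized)
  likelihood: high
  category: limb
  subgroup: Muscle strength
  patterns:
  - '728.87'
- label: Difficulty walking
  likelihood: high
  category: limb
  subgroup: Gait
  patterns:
  - '719.7'
- label: Gait abnormality
  likelihood: high
  category: limb
  subgroup: Gait
  patterns:
  - '781.2'
- label: Lack of coordination
  likelihood: high
  category: limb
  subgroup: Gait
  patterns:
  - '781.3'
- label: Cramping
  likelihood: high
  category: limb
  subgroup: Involuntary muscle movement
  patterns:
  - '729.82'
- label: Spasm
  likelihood: high
  category: limb
  subgroup: Involuntary muscle movement
  patterns:
  - '728.85'
- label: Twitching/fasciculation
  likelihood: high
  category: limb
  subgroup: Involuntary muscle movement
  patterns:
  - '781.0'
- label: Myopathy (including myopathy with weakness)
  likelihood: high
  category: limb
  subgroup: Myopathy
  patterns:
  - 359.X
- label: Pain in joint
  likelihood: moderate
  category: limb
  subgroup: Pain
  patterns:
  - '719.4'
- label: Pain in limb
  likelihood: moderate
  category: limb
  subgroup: Pain
  patterns:
  - '729.5'
- label: Disorder of muscle and/or ligament
  likelihood: moderate
  category: limb
  subgroup: Other
  patterns:
  - 728.X
groups:
- label: Speech disturbance
  group_kind: symptom_or_diagnosis
  patterns:
  - 784.5X
  symptom_group: bulbar
- label: Voice resonance disorder
  group_kind: symptom_or_diagnosis
  patterns:
  - 784.4X
  symptom_group: bulbar
- label: Muscle weakness (generalized)
  group_kind: symptom_or_diagnosis
  patterns:
  - '728.87'
  symptom_group: limb
- label: Lack of coordination
  group_kind: symptom_or_diagnosis
  patterns:
  - '781.3'
  symptom_group: limb
- label: Dysphagia
  group_kind: symptom_or_diagnosis
  patterns:
  - '787.2'
  - '438.82'
  symptom_group: bulbar
- label: Hereditary and idiopathic peripheral neuropathies
  group_kind: symptom_or_diagnosis
  patterns:
  - 356.X
  symptom_group: nerve
- label: Cervicalgia
  group_kind: symptom_or_diagnosis
  patterns:
  - '723.1'
  symptom_group: nerve
- label: Gait abnormality/difficulty walking
  group_kind: symptom_or_diagnosis
  patterns:
  - '781.2'
  - '719.7'
  symptom_group: limb
- label: Gait abnormality
  group_kind: symptom_or_diagnosis
  patterns:
  - '781.2'
  symptom_group: limb
- label: Difficulty in walking
  group_kind: symptom_or_diagnosis
  patterns:
  - '719.7'
  symptom_group: limb
- label: Transient cerebral ischemia
  group_kind: symptom_or_diagnosis
  patterns:
  - 435.X
  symptom_group: other
- label: Loss of weight
  group_kind: symptom_or_diagnosis
  patterns:
  - '783.21'
  symptom_group: other
- label: Stroke
  group_kind: symptom_or_diagnosis
  patterns:
  - 434.X
  - '436'
  symptom_group: other
- label: Lumbago/backache
  group_kind: symptom_or_diagnosis
  patterns:
  - '724.2'
  - '724.5'
  symptom_group: other
- label: Malaise and fatigue
  group_kind: symptom_or_diagnosis
  patterns:
  - 780.7X
  symptom_group: other
- label: Syncope and collapse
  group_kind: symptom_or_diagnosis
  patterns:
  - '780.2'
  symptom_group: other
- label: Pain in limb
  group_kind: symptom_or_diagnosis
  patterns:
  - '729.5'
  symptom_group: limb
- label: Esophageal reflux
  group_kind: symptom_or_diagnosis
  patterns:
  - '530.81'
  symptom_group: other
- label: Constipation
  group_kind: symptom_or_diagnosis
  patterns:
  - 564.0X
  symptom_group: other
- label: Pulmonary collapse/failure
  group_kind: symptom_or_diagnosis
  patterns:
  - '518.0'
  - 518.8X
  symptom_group: respiratory
- label: Dizziness and giddiness
  group_kind: symptom_or_diagnosis
  patterns:
  - '780.4'
  symptom_group: other
- label: Swelling in limb
  group_kind: symptom_or_diagnosis
  patterns:
  - '729.81'
  symptom_group: other
- label: Respiratory difficulties
  group_kind: symptom_or_diagnosis
  patterns:
  - 786.0X
  symptom_group: respiratory
- label: Hypothyroidism
  group_kind: symptom_or_diagnosis
  patterns:
  - 244.X
  symptom_group: other
- label: Nausea, vomiting, etc.
  group_kind: symptom_or_diagnosis
  patterns:
  - 787.0X
  symptom_group: other
- label: Pain in joint
  group_kind: symptom_or_diagnosis
  patterns:
  - '719.4'
  symptom_group: limb
- label: Bronchitis
  group_kind: symptom_or_diagnosis
  patterns:
  - '466.0'
  - '490'
  - 491.X
  symptom_group: respiratory
- label: Chronic airway obstruction
  group_kind: symptom_or_diagnosis
  patterns:
  - '496'
  symptom_group: respiratory
- label: Acute upper respiratory infection
  group_kind: symptom_or_diagnosis
  patterns:
  - 465.X
  symptom_group: respiratory
- label: Chronic inflammatory demyelinating polyneuropathy
  group_kind: symptom_or_diagnosis
  patterns:
  - '357.81'
  symptom_group: nerve
- label: Myopathy (including myopathy with weakness)
  group_kind: symptom_or_diagnosis
  patterns:
  - 359.X
  symptom_group: nerve
- label: Unspecified disease of spinal cord
  group_kind: symptom_or_diagnosis
  patterns:
  - '336.9'
  symptom_group: nerve
- label: Cervical/thoracic or lumbar spondylosis with myelopathy
  group_kind: symptom_or_diagnosis
  patterns:
  - '721.1'
  - '721.41'
  - '721.42'
  symptom_group: nerve
- label: Atrophy, muscular disuse
  group_kind: symptom_or_diagnosis
  patterns:
  - '728.2'
  symptom_group: limb
- label: Sensory nerve conduction test
  group_kind: diagnostic_test
  patterns:
  - NCT_SENSORY
- label: Motor nerve conduction test with F-wave
  group_kind: diagnostic_test
  patterns:
  - NCT_MOTOR_F
- label: Motor nerve conduction test without F-wave
  group_kind: diagnostic_test
  patterns:
  - NCT_MOTOR_NOF
- label: MRI of neck and spine without dye
  group_kind: diagnostic_test
  patterns:
  - MRI_NECK_SPINE
- label: CT scans (head or brain) with/without contrast material
  group_kind: diagnostic_test
  patterns:
  - CT_HEAD_BRAIN
- label: MRI of brain with/without dye
  group_kind: diagnostic_test
  patterns:
  - MRI_BRAIN
- label: Limb electromyography (2 extremities and related paraspinal areas)
  group_kind: diagnostic_test
  patterns:
  - EMG_LIMB_2
- label: Limb electromyography (1 extremity and related paraspinal areas)
  group_kind: diagnostic_test
  patterns:
  - EMG_LIMB_1
- label: Exam of throat and/or upper gastrointestinal tract
  group_kind: diagnostic_test
  patterns:
  - EXAM_THROAT_UGI
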