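[
  {
    "patient_id": "E01",
    "findings": [
      {
        "code": "hypotonia"
      },
      {
        "code": "ventilator_dependent_respiratory_weakness"
      }
    ],
    "neuromuscular_onset": "at_birth",
    "vital_status": "deceased",
    "prenatal_death": false,
    "age_at_death_months": 1.5,
    "liver_transplant": "unknown",
    "explicit_normal_hepatic": true,
    "explicit_normal_neuromuscular": false,
    "explicit_normal_cardiac": true
  },
  {
    "patient_id": "E02",
    "findings": [
      {
        "code": "hepatomegaly"
      },
      {
        "code": "elevated_alt"
      }
    ],
    "neuromuscular_onset": "unknown",
    "vital_status": "alive",
    "prenatal_death": false,
    "age_at_last_followup_months": 96,
    "liver_transplant": "unknown",
    "explicit_normal_hepatic": false,
    "explicit_normal_neuromuscular": true,
    "explicit_normal_cardiac": false
  },
  {
    "patient_id": "E03",
    "findings": [
      {
        "code": "liver_failure"
      },
      {
        "code": "jaundice"
      },
      {
        "code": "hepatomegaly"
      }
    ],
    "neuromuscular_onset": "unknown",
    "vital_status": "alive",
    "prenatal_death": false,
    "age_at_last_followup_months": 60,
    "liver_transplant": "yes",
    "age_at_transplant_months": 18,
    "explicit_normal_hepatic": false,
    "explicit_normal_neuromuscular": true,
    "explicit_normal_cardiac": true
  },
  {
    "patient_id": "E04",
    "findings": [
      {
        "code": "hypotonia"
      },
      {
        "code": "hepatomegaly"
      },
      {
        "code": "splenomegaly",
        "platelet_count": 110000
      }
    ],
    "neuromuscular_onset": "at_birth",
    "vital_status": "deceased",
    "prenatal_death": false,
    "age_at_death_months": 20,
    "liver_transplant": "unknown",
    "explicit_normal_hepatic": false,
    "explicit_normal_neuromuscular": false,
    "explicit_normal_cardiac": false,
    "death_attributed_hepatic": true
  },
  {
    "patient_id": "E05",
    "findings": [
      {
        "code": "cardiomyopathy"
      }
    ],
    "neuromuscular_onset": "unknown",
    "vital_status": "alive",
    "prenatal_death": false,
    "age_at_last_followup_months": 140,
    "liver_transplant": "unknown",
    "explicit_normal_hepatic": true,
    "explicit_normal_neuromuscular": true,
    "explicit_normal_cardiac": false
  },
  {
    "patient_id": "E06",
    "findings": [
      {
        "code": "hypotonia"
      }
    ],
    "neuromuscular_onset": "unknown",
    "vital_status": "alive",
    "prenatal_death": false,
    "age_at_last_followup_months": 30,
    "liver_transplant": "unknown",
    "explicit_normal_hepatic": false,
    "explicit_normal_neuromuscular": false,
    "explicit_normal_cardiac": false
  }
]
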