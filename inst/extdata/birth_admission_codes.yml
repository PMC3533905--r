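# ICD-10-AM diagnosis and ACHI procedure code lists used to identify
# hospital birth admissions (infants and mothers) and to derive clinical
# variables from coded hospital records.
#
# Diagnosis entries are hierarchical prefixes ("O24" matches O24.4) or
# ranges within a letter class ("O80-O84", "Z37.2-Z37.7"). Procedure
# entries are 5-digit ACHI codes or numeric ranges.
#
# Note: the duration-of-pregnancy rule (O90.1-O90.3) is printed against a
# "< 25 weeks" label in the identification table but the variable list and
# comparison tables use "< 26 weeks"; outputs use the key duration_lt26wk
# and this file records both labels.
infant_birth_admission:
  liveborn_by_place: ["Z38"]
  perinatal_condition: ["P00-P96"]
  age_days: [0, 1]
maternal_delivery_admission:
  diagnosis:
    delivery: ["O80-O84"]
    outcome_of_delivery: ["Z37"]
    preterm_delivery: ["O60.1-O60.3"]
  procedure:
    delivery_procedures: ["90467-90470", "16520"]
    postpartum_sutures: ["16571", "16573", "90479-90481", "90485"]
    other_procedures_associated_with_delivery: ["90472-90477"]
    analgesia_anaesthesia_labour_delivery: ["92506", "92507"]
    induction_augmentation_of_labour: ["90465", "90466"]
variables:
  preterm:
    diagnosis: ["P07.2", "P07.3"]
  apgar1_lt4:
    diagnosis: ["P20.1"]
  diabetes:
    diagnosis: ["O24", "E10", "E11", "E13", "E14"]
  hypertension:
    diagnosis: ["O10", "O11", "O13-O16"]
  induction:
    procedure: ["90465"]
  caesarean:
    diagnosis: ["O82"]
    procedure: ["16520"]
  placenta_praevia:
    diagnosis: ["O44.1"]
  placental_abruption:
    diagnosis: ["O45"]
  duration_lt26wk:            # printed label "< 25 weeks" in the rule table
    diagnosis: ["O90.1", "O90.2", "O90.3"]
plurality:
  singleton:
    diagnosis: ["Z37.0-Z37.1", "Z38.0-Z38.2", "O80-O83"]
  multiple:
    diagnosis: ["Z37.2-Z37.7", "Z38.3-Z38.8", "O84"]
stillbirth:
  diagnosis: ["Z37.1", "Z37.3", "Z37.4", "Z37.6", "Z37.7"]
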