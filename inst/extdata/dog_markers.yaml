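# Default canine CBC + serum chemistry panel configuration (28 analytes).
# Reference intervals are editable population defaults in the style of
# clinical-pathology laboratory intervals; replace with your laboratory's
# values before interpreting out-of-range counts clinically.
# log_transform marks the nine right-skewed analytes modelled on the ln scale.
wbc:              {units: "10^3/uL", log_transform: false, reference_low: 6.0,   reference_high: 17.0}
rbc:              {units: "10^6/uL", log_transform: false, reference_low: 5.5,   reference_high: 8.5}
hgb:              {units: "g/dL",    log_transform: false, reference_low: 12.0,  reference_high: 18.0}
hct:              {units: "%",       log_transform: false, reference_low: 37.0,  reference_high: 55.0}
mcv:              {units: "fL",      log_transform: false, reference_low: 60.0,  reference_high: 77.0}
mch:              {units: "pg",      log_transform: false, reference_low: 19.5,  reference_high: 24.5}
mchc:             {units: "g/dL",    log_transform: false, reference_low: 32.0,  reference_high: 36.0}
plt:              {units: "10^3/uL", log_transform: false, reference_low: 200.0, reference_high: 500.0}
neutrophils:      {units: "10^3/uL", log_transform: false, reference_low: 3.0,   reference_high: 11.5}
lymphocytes:      {units: "10^3/uL", log_transform: false, reference_low: 1.0,   reference_high: 4.8}
monocytes:        {units: "10^3/uL", log_transform: false, reference_low: 0.15,  reference_high: 1.35}
glucose:          {units: "mg/dL",   log_transform: false, reference_low: 70.0,  reference_high: 120.0}
urea_nitrogen:    {units: "mg/dL",   log_transform: true,  reference_low: 7.0,   reference_high: 27.0}
creatinine:       {units: "mg/dL",   log_transform: true,  reference_low: 0.5,   reference_high: 1.5}
total_protein:    {units: "g/dL",    log_transform: false, reference_low: 5.4,   reference_high: 7.4}
albumin:          {units: "g/dL",    log_transform: false, reference_low: 2.7,   reference_high: 4.0}
globulin:         {units: "g/dL",    log_transform: false, reference_low: 2.0,   reference_high: 4.0}
alp:              {units: "U/L",     log_transform: true,  reference_low: 20.0,  reference_high: 150.0}
alt:              {units: "U/L",     log_transform: true,  reference_low: 10.0,  reference_high: 100.0}
ast:              {units: "U/L",     log_transform: true,  reference_low: 15.0,  reference_high: 55.0}
ggt:              {units: "U/L",     log_transform: true,  reference_low: 1.0,   reference_high: 10.0}
bilirubin:        {units: "mg/dL",   log_transform: true,  reference_low: 0.05,  reference_high: 0.5}
cholesterol:      {units: "mg/dL",   log_transform: false, reference_low: 110.0, reference_high: 320.0}
triglycerides:    {units: "mg/dL",   log_transform: true,  reference_low: 25.0,  reference_high: 150.0}
creatine_kinase:  {units: "U/L",     log_transform: true,  reference_low: 50.0,  reference_high: 400.0}
calcium:          {units: "mg/dL",   log_transform: false, reference_low: 9.0,   reference_high: 11.5}
phosphorus:       {units: "mg/dL",   log_transform: false, reference_low: 2.5,   reference_high: 6.0}
sodium:           {units: "mEq/L",   log_transform: false, reference_low: 140.0, reference_high: 153.0}
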