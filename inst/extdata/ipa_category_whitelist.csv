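category
Hepatocellular carcinoma
Liver Cholestasis
Liver Hyperplasia/Hyperproliferation
Liver Inflammation/Hepatitis
Liver Necrosis/Cell Death
Liver Proliferation
Liver Steatosis
Liver Damage
Liver Fibrosis
Liver Failure
Liver Cirrhosis
Liver Regeneration
Glomerular Injury
Renal Inflammation
Renal Nephritis
Renal Damage
Renal Tubule Injury
Renal Necrosis/Cell Death
Renal Proliferation
Renal Failure
Renal Fibrosis
Renal Hypertrophy
Renal Regeneration
Kidney Failure
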