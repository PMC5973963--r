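# Shared level sets and naming conventions (loaded before the module files).

.eta_names <- c("ka", "cl", "vc", "f1")
.sex_levels <- c("male", "female")
.race_levels <- c("White", "Black", "Asian", "Other")
.pop_levels <- c("HV", "RCC", "CRPC", "MTC", "GB", "OTH")
.form_levels <- c("tablet", "capsule")
.fc_levels <- c("female", "Black", "Asian", "Other",
                "RCC", "CRPC", "MTC", "GB", "OTH")
.lloq_default <- 0.5  # ng/mL
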