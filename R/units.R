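# Unit conversion constants. All public interfaces use mmHg, mm, cm/s, mL/s, s;
# the solver works internally in SI (Pa, m, m^3/s).

MMHG_TO_PA <- 133.322
MM_TO_M <- 1e-3
MM2_TO_M2 <- 1e-6
M_S_TO_CM_S <- 100
ML_S_TO_M3_S <- 1e-6

# mmHg.s/mL -> Pa.s/m^3
RES_MMHG_ML_TO_SI <- MMHG_TO_PA / ML_S_TO_M3_S
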