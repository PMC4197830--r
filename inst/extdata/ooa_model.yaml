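# Default three-population out-of-Africa demographic model.
# Values approximate the published calibration of low-coverage phase-I
# sequence data (Gravel et al. 2011, PNAS 108:11983); see ?demographic_model.
N_anc: 7310        # ancestral diploid effective size
N_af: 14474        # modern African size from T_af onwards
N_b: 1861          # out-of-Africa bottleneck size
N_eu0: 1032        # European size at the EUR/ASN split
N_as0: 554         # East-Asian size at the EUR/ASN split
g_eu: 0.0038       # European exponential growth per generation
g_as: 0.0048       # East-Asian exponential growth per generation
T_af: 5920         # generations ago: African growth
T_b: 2040          # generations ago: out-of-Africa split
T_eu_as: 920       # generations ago: EUR/ASN split
m_af_b: 1.5e-4     # symmetric migration AFR <-> B
m_af_eu: 2.5e-5    # symmetric migration AFR <-> EUR
m_af_as: 7.8e-6    # symmetric migration AFR <-> ASN
m_eu_as: 3.11e-5   # symmetric migration EUR <-> ASN
mu: 2.36e-8        # mutation rate per bp per generation
rec: 1.25e-8       # recombination rate per bp per generation (1.25 cM/Mb)
lambda: 10         # population-size rescaling factor
burnin_factor: 8   # burn-in, in units of the rescaled ancestral size
npop: 3
m_scale: 1
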