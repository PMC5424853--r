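# Transition-probability assumptions of the manufacturer's monthly-cycle
# Markov cohort model for the CLL-8 comparison.  The progression -> death
# probability is constant, derived from the reciprocal of the Kaplan-Meier
# mean post-progression survival of 24.1791 months; progression-free -> death
# uses the observed monthly probability per arm (or an age-specific
# background mortality probability, whichever is larger, when a life table is
# supplied); staying in progression-free follows the same Weibull
# progression-free survival regression as the partitioned approach.
post_progression_km_mean_months: 24.1791
p_pf_death_monthly:
  RFC: 0.0012
  FC: 0.00139
pfs:
  family: weibull
  params: {log_scale: 1.237, log_shape: 0.310}
  coefficients: {treat: -0.519}
horizon: 15
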