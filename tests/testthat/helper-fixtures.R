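# Shared fixtures, built in code.

# SEC standards: 2500/500/150 kDa with peak positions at fraction centers.
sec_standards <- function() {
  data.frame(mw_kda = c(2500, 500, 150), position = c(8, 14, 20))
}

# Agarose ladder: 200/400/1260/2500/3900 kDa vs migration distance
# (largest migrates least).
gel_ladder <- function() {
  data.frame(mw_kda = c(3900, 2500, 1260, 400, 200),
             position = c(1.0, 1.8, 3.0, 5.2, 6.5))
}

# Two-component HA mixture: 70% of mass well above 500 kDa, 30% well below
# 150 kDa; continuous-truth HMW/LMW ratio is exactly 7/3.
hmw_lmw_mixture <- function() {
  data.frame(mean_log10_mw = c(log10(1500), log10(50)),
             sd_log10_mw = c(0.05, 0.08),
             mass_fraction = c(0.7, 0.3))
}

# Independent brute-force oracle for the sign-weighted Fisher statistic:
# plain loop, no vectorized shortcut shared with the implementation.
brute_force_signed_logsum <- function(pvals, logfcs) {
  acc <- 0
  for (i in seq_along(pvals)) {
    w <- if (logfcs[i] > 0) 1 else if (logfcs[i] < 0) -1 else 0
    acc <- acc + log(pvals[i]) * w
  }
  abs(acc)
}
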