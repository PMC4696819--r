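# Shared objects for the suite: the canonical fixed-seed datasets and the
# fits that several test files reuse.  Everything is generated in code.

fx <- dr_fixtures()

fit_ll4_clean <- dr_fit_ls(fx$ll4_clean, "LL.4")
fit_ll2_binom <- dr_fit_ml(fx$ll2_binom, "LL.2", family = "binomial")

# noiseless LL.4 data and fit (exact-recovery oracle)
ll4_true <- c(b = 2, c = 0.1, d = 0.9, e = 3)
ll4_doses <- 0.125 * 2^(0:7)
noiseless_ll4 <- dr_simulate("LL.4", ll4_true, doses = ll4_doses, reps = 4,
                             sd = 0, seed = 1)
fit_noiseless <- dr_fit_ls(noiseless_ll4, "LL.4")

# random admissible parameter vectors for the sigmoid families, used by
# property-style loops (b spans both signs, c < d, e positive)
random_beta4 <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    c(b = sample(c(-1, 1), 1) * stats::runif(1, 0.3, 4),
      c = stats::runif(1, -0.5, 0.4),
      d = stats::runif(1, 0.6, 2),
      e = exp(stats::runif(1, log(0.05), log(50))))
  })
}
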