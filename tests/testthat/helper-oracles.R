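# Independent numerical oracles used across tests.

# Studentized-range CDF by direct numerical integration (independent of
# stats::ptukey): P(Q <= q) for the range of k standard normals divided by
# an independent chi-based scale estimate on df degrees of freedom.
ptukey_oracle <- function(q, k, df) {
  prange <- function(x) {
    # P(range of k iid std normals <= x)
    f <- function(z) stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - x))^(k - 1)
    k * stats::integrate(f, -10, 10, rel.tol = 1e-10)$value
  }
  # density of S = sqrt(chi2_df / df)
  gs <- function(s) {
    exp((df / 2) * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2) +
          (df - 1) * log(s) - df * s^2 / 2)
  }
  stats::integrate(Vectorize(function(s) gs(s) * prange(q * s)),
                   0, Inf, rel.tol = 1e-8)$value
}

# Minimal valid coral-sample table for constructing fixtures in code.
make_samples <- function(n = 4, w0 = 10, w1 = 9.9, surface_area = 100,
                         volume = 10, duration = 7,
                         genus = "Montipora", growth_form = "foliose",
                         porosity_class = "perforate",
                         treatment = "acidified") {
  data.frame(sample_id = sprintf("T%02d", seq_len(n)),
             genus = genus, growth_form = growth_form,
             porosity_class = porosity_class, treatment = treatment,
             w0 = w0, w1 = w1, surface_area = surface_area,
             volume = volume, duration = duration,
             stringsAsFactors = FALSE)
}
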