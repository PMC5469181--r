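# Shared fixtures: the mouse small-intestine crypt and the yeast
# mutation-accumulation DFE used throughout the analyses.

mouse_crypt <- function() crypt_parameters(X1 = 6, lam = 0.2, nu = 1 / 3,
                                           gamma = 2, delta = 1 / 3, R = 6)

yeast <- function() dfe_yeast()

# random homeostatic crypt parameter sets for property-style loops
random_crypt <- function() {
  lam <- runif(1, 0.05, 0.5)
  crypt_parameters(X1 = sample(2:20, 1), lam = lam,
                   nu = lam * runif(1, 1.2, 4),
                   gamma = runif(1, 0.5, 4), delta = runif(1, 0.1, 1),
                   R = sample(2:7, 1))
}
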