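## small shared fixtures, built in code

tiny_config <- function(K_max = 10, n_iter = 500, burn_in = 100, seed = 1,
                        ...) {
  mcmc_config(K_max = K_max, n_iter = n_iter, burn_in = burn_in,
              seed = seed, ...)
}

## independent dense evaluation of a normal mixture log density
mixture_logdens <- function(y, lambda, means, vars) {
  vapply(y, function(yi)
    log(sum(lambda * dnorm(yi, means, sqrt(vars)))), 0)
}

b2_model <- function() {
  growth_model_spec(class_specific = "intercept", common = "time",
                    random = "intercept")
}

b3_model <- function() {
  growth_model_spec(class_specific = c("intercept", "time"),
                    random = c("intercept", "time"))
}
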