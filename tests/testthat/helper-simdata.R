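# seeded draws from a Gaussian mixture with one row of `centers` per component
sim_mixture <- function(n_per, centers, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(g) {
      matrix(stats::rnorm(n_per * ncol(centers), mean = 0, sd = sd),
             n_per, ncol(centers)) +
        matrix(centers[g, ], n_per, ncol(centers), byrow = TRUE)
    }))
  })
  rownames(x) <- sprintf("OBS%04d", seq_len(nrow(x)))
  x
}
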