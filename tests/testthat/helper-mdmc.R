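# Shared fixtures: preset parameter sets and the nine-cell condition list.

vt_conditions <- all_conditions(c("visual", "tactile"))

# small deterministic trial table spanning all nine conditions
toy_table <- function(n_per_condition = 20, seed = 42) {
  set.seed(seed)
  rows <- lapply(names(vt_conditions), function(cc) {
    cond <- vt_conditions[[cc]]
    data.frame(participant = 1L,
               visual = unname(cond[["visual"]]),
               tactile = unname(cond[["tactile"]]),
               rt = runif(n_per_condition, 250, 900),
               accuracy = rbinom(n_per_condition, 1, 0.9),
               censored = FALSE)
  })
  do.call(rbind, rows)
}
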