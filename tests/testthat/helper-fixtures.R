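# Shared fixtures built in code: tiny matrices with known statistics, a
# deterministic drug-class annotation, and a 4PL viability sampler.

toy_expression <- function(p = 10L, n = 8L, seed = 42L) {
  set.seed(seed)
  X <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("g%02d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  X
}

toy_response <- function(q = 3L, n = 8L, seed = 43L) {
  set.seed(seed)
  matrix(runif(q * n), q, n,
         dimnames = list(sprintf("d%02d", seq_len(q)),
                         sprintf("s%02d", seq_len(n))))
}

toy_classes <- function() {
  structure(list(d01 = "kinase", d02 = c("kinase", "hdac"), d03 = "hdac",
                 d04 = "anthracycline", d05 = "anthracycline",
                 d06 = "anthracycline"),
            class = "drug_class_annotation")
}

# Viability from a 4PL curve at 8 log-spaced molar concentrations.
viability_4pl <- function(top = 1, bottom = 0, ec50 = 1e-7, hill = 1,
                          conc = 10^seq(-10, -5, length.out = 8L),
                          noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- bottom + (top - bottom) / (1 + 10^(hill * (log10(conc) - log10(ec50))))
  list(conc = conc, v = pmax(v + rnorm(length(conc), 0, noise_sd), 0))
}

write_tsv_matrix <- function(x, path) {
  mergeaml::write_matrix(x, path)
  path
}
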