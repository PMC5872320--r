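# shared generators for property-style tests

random_dissimilarity <- function(n) {
  m <- matrix(runif(n * n, 0.05, 1), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  m
}

random_presence <- function(n_samples, n_species, p = 0.4) {
  m <- matrix(rbinom(n_samples * n_species, 1, p), n_samples, n_species)
  rownames(m) <- paste0("s", seq_len(n_samples))
  m
}

make_records <- function(plant, fragment, species, medium = "PDA",
                         stem_age = "unspecified") {
  data.frame(plant_id = plant, island = "I", locality = "L",
             medium = medium, stem_age = stem_age,
             fragment_id = fragment, species = species,
             stringsAsFactors = FALSE)
}
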