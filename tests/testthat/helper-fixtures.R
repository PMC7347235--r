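# Small in-code fixtures shared across test files.

toy_variants <- function() {
  validate_variants(data.frame(
    variant_id = c("v1", "v2", "v3"),
    protein_change = c("p.A1B", "p.C2D", "p.E3F"),
    residue_index = c(1L, 2L, 3L),
    variant_class = "missense",
    n_affected = c(2L, 0L, 5L),
    n_unaffected_lit = c(1L, 0L, 2L),
    n_gnomad = c(0L, 10L, 3L),
    peak_current = c(0.9, NA, 0.2),
    penetrance_density = c(0.1, 0.5, 0.8),
    sift = c(0.2, 0.4, NA),
    polyphen2 = c(0.1, 0.9, NA),
    provean = c(-1, -4, NA),
    blast_pssm = c(1, 3, NA),
    evolutionary_rate = c(0.5, 1.2, NA),
    pam = c(2, 5, NA)))
}

toy_csv <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy.csv")
  write_dataset(toy_variants(), path)
  path
}

# A small fully observed cohort with an exact linear penetrance surface.
exact_linear_cohort <- function(n = 60, seed = 2) {
  set.seed(seed)
  pc <- runif(n, 0.2, 1.2)
  pd <- runif(n, 0, 1)
  validate_variants(data.frame(
    variant_id = sprintf("lin_%03d", seq_len(n)),
    residue_index = seq_len(n),
    variant_class = "missense",
    n_affected = rbinom(n, 20, 0.3),
    n_unaffected_lit = 10L,
    n_gnomad = 10L,
    peak_current = pc, penetrance_density = pd,
    sift = NA_real_, polyphen2 = NA_real_, provean = NA_real_,
    blast_pssm = NA_real_, evolutionary_rate = NA_real_, pam = NA_real_))
}
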