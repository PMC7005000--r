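# Shared fixtures, built in code at test time.

suppressPackageStartupMessages(library(dplyr))

# Small genome + annotation + library used by several files.
toy_world <- function(len = 20000, n_genes = 12, mean_gene_len = 800,
                      seed = 42) {
  genome <- make_genome(len, gc = 0.5, seed = seed)
  ann <- make_annotation(genome, n_genes, mean_gene_len, seed = seed + 1)
  lib <- make_library(ann, density = 1 / 20, seed = seed + 2)
  list(genome = genome, ann = ann, lib = lib)
}

two_sample_scenario <- function(baseline = 0.5, survival_factor = numeric(0),
                                plating = c(control = 1e5, treated = 5e4),
                                depth = c(control = 1e6, treated = 1e6),
                                seed = 1) {
  selection_scenario(survival_factor = survival_factor,
                     baseline_survival = c(treated = baseline),
                     plating_counts = plating, read_depth = depth,
                     seed = seed)
}

# A hand-built 3-gene GenBank fixture (500 bp, with complement and join
# locations and a CDS duplicating a gene).
write_toy_genbank <- function(path) {
  writeLines(c(
    "LOCUS       toychr 500 bp    DNA     linear   UNA",
    "DEFINITION  toy chromosome",
    "FEATURES             Location/Qualifiers",
    "     source          1..500",
    "     gene            101..200",
    '                     /locus_tag="tg001"',
    '                     /gene="alpha"',
    "     CDS             101..200",
    '                     /locus_tag="tg001"',
    "     gene            complement(251..310)",
    '                     /locus_tag="tg002"',
    "     CDS             join(351..380,401..450)",
    '                     /locus_tag="tg003"',
    "//"), path)
  path
}

# A hand-built SAM fixture: header + records covering forward, reverse,
# unmapped, secondary flags.
write_toy_sam <- function(path, extra = character(0)) {
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:toychr\tLN:500",
    "r1\t0\ttoychr\t101\t42\t30M\t*\t0\t0\t*\t*",
    "r2\t16\ttoychr\t101\t42\t30M\t*\t0\t0\t*\t*",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "r4\t256\ttoychr\t11\t42\t30M\t*\t0\t0\t*\t*",
    "r5\t0\ttoychr\t201\t42\t10M5D20M\t*\t0\t0\t*\t*",
    extra), path)
  path
}

# Brute-force aggregation oracle: nested loops over sites and features,
# membership by position only, wrap-around features handled modulo L.
oracle_aggregate <- function(sites, ann) {
  f <- ann$features
  L <- ann$genome$length
  out <- list()
  for (sm in unique(sites$sample_id)) {
    ss <- sites[sites$sample_id == sm, ]
    for (j in seq_len(nrow(f))) {
      inside <- logical(nrow(ss))
      for (i in seq_len(nrow(ss))) {
        p <- ss$position[i]
        inside[i] <- (p >= f$start[j] && p < f$end[j]) ||
          (f$end[j] > L && p < f$end[j] - L)
      }
      out[[length(out) + 1]] <- tibble::tibble(
        feature_id = f$feature_id[j], sample_id = sm,
        n_sites = sum(inside & ss$count > 0),
        actual_reads = sum(ss$count[inside]))
    }
  }
  dplyr::bind_rows(out) |> dplyr::arrange(feature_id, sample_id)
}

# Expected treated/control frequency ratio per feature under the selection
# model, by direct enumeration over the site list (independent of the
# multinomial sampling code).
oracle_freq_ratio <- function(lib, ann, survival_factor, baseline) {
  f <- ann$features
  L <- ann$genome$length
  s <- rep(1, nrow(lib))
  for (j in seq_len(nrow(f))) {
    fac <- survival_factor[f$feature_id[j]]
    if (is.na(fac)) next
    inside <- (lib$position >= f$start[j] & lib$position < f$end[j]) |
      (f$end[j] > L & lib$position < f$end[j] - L)
    s[inside] <- s[inside] * fac
  }
  # equal inoculum per site; control frequencies uniform
  ratio_site <- s / mean(s)
  vapply(seq_len(nrow(f)), function(j) {
    inside <- (lib$position >= f$start[j] & lib$position < f$end[j]) |
      (f$end[j] > L & lib$position < f$end[j] - L)
    if (!any(inside)) return(NA_real_)
    mean(ratio_site[inside])
  }, numeric(1))
}
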