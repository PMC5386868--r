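# Shared fixtures: a small genome keeps simulation-heavy tests fast while
# preserving the NOR layout (NOR2/NOR4 at the tops of chromosomes 2 and 4,
# baseline on chromosome 3).
test_genome <- function(n_chrom = 4, length_bp = 1e6, length_cM = 50,
                        window_size = 1e5) {
  genome_model(
    chromosomes = data.frame(name = paste0("chr", seq_len(n_chrom)),
                             length_bp = length_bp, length_cM = length_cM),
    window_size_bp = window_size,
    nor_positions = c(NOR2 = "chr2", NOR4 = "chr4"),
    baseline_region = list(chrom = "chr3", start = 0, end = 5e5))
}

# Independent scalar re-statement of the window classification rules,
# written as a literal if-chain; used as a brute-force oracle.
oracle_call_window <- function(n_seg, n_called, n_mat, n_pat, n_het) {
  if (n_seg < 100) return(NA_character_)
  if (n_called < 40) return(NA_character_)
  if (n_mat / n_called > 0.90) return("A")
  if (n_pat / n_called > 0.90) return("B")
  if (n_het / n_called > 0.25) return("H")
  if (abs(n_mat - n_pat) / n_called < 0.30) return("H")
  NA_character_
}

# Minimal hand-built genotype objects for probability/scan tests.
manual_geno_matrix <- function(calls, chrom = "chr1") {
  windows <- data.frame(chrom = chrom,
                        window_index = seq_len(ncol(calls)) - 1L,
                        call_rate = colMeans(!is.na(calls)))
  structure(list(calls = calls, windows = windows,
                 samples = rownames(calls)),
            class = "nor_geno_matrix")
}

manual_map <- function(cM, chrom = "chr1", design = "F2") {
  structure(data.frame(chrom = chrom,
                       window_index = seq_along(cM) - 1L,
                       bp = (seq_along(cM) - 1L) * 1e5, cM = cM),
            class = c("nor_genetic_map", "data.frame"),
            design = design, map_function = "haldane")
}
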