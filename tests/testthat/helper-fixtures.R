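# Fixture builders used across test files.  Everything is generated in
# code under fixed seeds; nothing is read from disk.

rnd_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# the standard small JAZF1/SUZ12-like fixture (5-exon A, 16-exon B,
# intron 3 of A = 2700 nt, intron 1 of B = 135 nt at scale 0.05)
preset_gen <- function(seed = 7, scale = 0.05) {
  generate_genome(fusion_preset(scale = scale, seed = seed))
}

# hand-built two-gene genome with `n_stems` perfect planted stems, one
# per matching intron pair; introns are 400 nt, exons 120 nt
multi_stem_fixture <- function(n_stems = 3, stem_len = 24, seed = 101) {
  set.seed(seed)
  n_exons <- n_stems + 1
  build <- function() {
    pieces <- c(rnd_dna(200))
    exons <- data.frame(start = integer(0), end = integer(0))
    pos <- 200L
    for (k in seq_len(n_exons)) {
      pieces <- c(pieces, rnd_dna(120))
      exons <- rbind(exons, data.frame(start = pos, end = pos + 120L))
      pos <- pos + 120L
      if (k < n_exons) { pieces <- c(pieces, rnd_dna(400)); pos <- pos + 400L }
    }
    pieces <- c(pieces, rnd_dna(200))
    list(seq = paste(pieces, collapse = ""), exons = exons)
  }
  a <- build(); b <- build()
  gene_a <- gene_model("gA", "cA", "+", a$exons)
  gene_b <- gene_model("gB", "cB", "+", b$exons)
  seq_a <- a$seq; seq_b <- b$seq
  ia <- introns_of(gene_a); ib <- introns_of(gene_b)
  planted <- list()
  for (k in seq_len(n_stems)) {
    a0 <- ia$start[k] + 180L
    win <- substr(seq_a, a0 + 1, a0 + stem_len)
    b0 <- ib$start[k] + 180L
    seq_b <- paste0(substr(seq_b, 1, b0), rc_chr(win),
                    substr(seq_b, b0 + stem_len + 1, nchar(seq_b)))
    planted[[k]] <- list(a = c(a0, a0 + stem_len), b = c(b0, b0 + stem_len))
  }
  list(genome = c(cA = seq_a, cB = seq_b), gene_a = gene_a, gene_b = gene_b,
       planted = planted)
}

# overlap of [s1,e1) with [s2,e2)
ov_len <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))
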