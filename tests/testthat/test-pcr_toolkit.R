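test_that("a constructed template yields exactly one amplicon", {
  set.seed(9)
  F <- primer("F", rnd_dna(20)); R <- primer("R", rnd_dna(20))
  mid <- rnd_dna(100)
  tpl <- paste0(F$sequence, mid, rc_chr(R$sequence))
  am <- ispcr(tpl, F, R)
  expect_equal(nrow(am), 1L)
  expect_equal(am$length, 140L)
  expect_equal(am$start, 0L)
  expect_identical(am$sequence, tpl)
  # absent primers: no product
  expect_equal(nrow(ispcr(rnd_dna(300), F, R)), 0L)
  # a too-long product is filtered
  expect_equal(nrow(ispcr(tpl, F, R, max_product = 100)), 0L)
})

test_that("ispcr agrees with a naive quadratic oracle on 200 random templates", {
  set.seed(333)
  for (k in 1:200) {
    n <- sample(120:260, 1)
    tpl <- rnd_dna(n)
    F <- primer("F", rnd_dna(sample(16:22, 1)))
    R <- primer("R", rnd_dna(sample(16:22, 1)))
    mode <- k %% 4
    if (mode == 0) {                     # plant one clean site pair
      f0 <- sample(0:30, 1); r0 <- sample(70:(n - 25), 1)
      substr(tpl, f0 + 1, f0 + nchar(F$sequence)) <- F$sequence
      substr(tpl, r0 + 1, r0 + nchar(R$sequence)) <- rc_chr(R$sequence)
    } else if (mode == 1) {              # plant two forward sites
      substr(tpl, 1, nchar(F$sequence)) <- F$sequence
      substr(tpl, 41, 40 + nchar(F$sequence)) <- F$sequence
      substr(tpl, n - nchar(R$sequence) + 1, n) <- rc_chr(R$sequence)
    } else if (mode == 2) {              # near-miss: one internal mismatch
      fmut <- F$sequence
      substr(fmut, 8, 8) <- setdiff(c("A", "C", "G", "T"),
                                    substr(fmut, 8, 8))[1]
      substr(tpl, 11, 10 + nchar(fmut)) <- fmut
      substr(tpl, n - nchar(R$sequence) + 1, n) <- rc_chr(R$sequence)
    }                                    # mode 3: nothing planted
    mm <- sample(0:1, 1)
    got <- ispcr(tpl, F, R, max_mismatch = mm)
    want <- naive_ispcr(tpl, F$sequence, R$sequence, max_mismatch = mm)
    expect_equal(got[c("start", "end")],
                 want[c("start", "end")],
                 ignore_attr = TRUE, info = paste("case", k))
  }
})

test_that("mismatched 3' pentamers never prime even with mismatch budget", {
  set.seed(11)
  F <- primer("F", rnd_dna(20)); R <- primer("R", rnd_dna(20))
  tpl <- paste0(F$sequence, rnd_dna(80), rc_chr(R$sequence))
  # corrupt the template base under the forward primer's 3' end
  bad <- tpl
  substr(bad, 20, 20) <- setdiff(c("A", "C", "G", "T"), substr(bad, 20, 20))[1]
  expect_equal(nrow(ispcr(bad, F, R, max_mismatch = 1)), 0L)
  # but an internal mismatch is tolerated at max_mismatch = 1
  bad2 <- tpl
  substr(bad2, 8, 8) <- setdiff(c("A", "C", "G", "T"), substr(bad2, 8, 8))[1]
  expect_equal(nrow(ispcr(bad2, F, R, max_mismatch = 1)), 1L)
  expect_equal(nrow(ispcr(bad2, F, R, max_mismatch = 0)), 0L)
})

test_that("three-round nested PCR reproduces the two-band pattern", {
  gen <- preset_gen()
  mat <- generate_fusion_materials(gen)
  tx <- splice_fusion_transcript(mat$alleles[["x"]])
  s <- tx$mature_sequence
  jp <- tx$junction_pos
  F1 <- primer("3F1", substr(s, jp - 180, jp - 161))
  F2 <- primer("3F2", substr(s, jp - 140, jp - 121))
  F3 <- primer("3F3", substr(s, jp - 110, jp - 91))
  R1 <- primer("3R1", rc_chr(substr(s, jp + 160, jp + 179)))
  R2 <- primer("3R2", rc_chr(substr(s, jp + 120, jp + 139)))
  sch <- nested_scheme(list(
    list(forward = F1, reverse = R1),
    list(forward = F2, reverse = R2),
    list(forward = list(F2, F3), reverse = R2)))
  rounds <- nested_pcr(s, sch)
  expect_length(rounds, 3)
  final <- rounds[[3]]
  expect_equal(nrow(final), 2L)
  # two products share their 3' end; length difference = F2->F3 distance
  expect_equal(length(unique(final$root_end)), 1L)
  expect_equal(abs(diff(final$length)), 30)
  expect_setequal(final$forward, c("3F2", "3F3"))
  # nesting: every later-round product lies within a previous product
  for (r in 2:3) {
    prev <- rounds[[r - 1]]
    for (i in seq_len(nrow(rounds[[r]]))) {
      expect_true(any(rounds[[r]]$root_start[i] >= prev$root_start &
                        rounds[[r]]$root_end[i] <= prev$root_end))
    }
  }
  # wild-type transcripts of either gene give no product in any round
  for (wt in list(mature_mrna(gen$gene_a, gen$genome),
                  mature_mrna(gen$gene_b, gen$genome))) {
    expect_true(all(vapply(nested_pcr(wt, sch), nrow, integer(1)) == 0L))
  }
})

test_that("tiling spacing follows the arithmetic contract", {
  set.seed(55)
  genome <- c(cA = rnd_dna(1400), cB = rnd_dna(1400))
  ga <- gene_model("gA", "cA", "+",
                   data.frame(start = c(50, 1150), end = c(100, 1250)))
  gb <- gene_model("gB", "cB", "+",
                   data.frame(start = c(50, 1150), end = c(100, 1250)))
  ia <- introns_of(ga); ib <- introns_of(gb)   # introns of length 1050
  tl <- design_tiling(interval("cA", 100, 1100, "+"),
                      interval("cB", 100, 1100, "+"), genome, 10, 5)
  expect_equal(nrow(tl$forward), 10L)
  expect_equal(tl$spacing_a, 100L)             # L = 1000, n = 10
  expect_equal(nrow(tl$reverse), 5L)
  expect_error(design_tiling(interval("cA", 100, 110, "+"), ib[1, ],
                             genome, 2, 2), "too short")
})

test_that("the 56 x 10 tiling of the preset introns is unique and intronic", {
  gen <- preset_gen()
  ia <- introns_of(gen$gene_a); ib <- introns_of(gen$gene_b)
  tl <- design_tiling(ia[3, ], ib[1, ], gen$genome, 56, 10)
  expect_equal(nrow(tl$forward), 56L)
  expect_equal(nrow(tl$reverse), 10L)
  # all sites intronic and sorted
  expect_true(all(tl$forward$start >= ia$start[3] & tl$forward$end <= ia$end[3]))
  expect_true(all(tl$reverse$start >= ib$start[1] & tl$reverse$end <= ib$end[1]))
  expect_true(!is.unsorted(tl$forward$start))
  # every emitted 20-mer site is unique in the two-locus union (both
  # strands), checked with an exhaustive k-mer table
  kmers <- function(s, k = 20) {
    n <- nchar(s)
    vapply(1:(n - k + 1), function(i) substr(s, i, i + k - 1), character(1))
  }
  tab <- table(c(unlist(lapply(gen$genome, kmers)),
                 unlist(lapply(lapply(gen$genome, rc_chr), kmers))))
  site_seqs <- c(tl$forward$sequence,
                 vapply(tl$reverse$sequence, rc_chr, character(1)))
  # each plus-strand site 20-mer occurs exactly once over both strands
  # of the two-locus union
  expect_true(all(tab[site_seqs] == 1L))
})

test_that("breakpoint scanning finds fusion-specific pairs bracketing the junction", {
  gen <- preset_gen()
  mat <- generate_fusion_materials(gen)
  ia <- introns_of(gen$gene_a); ib <- introns_of(gen$gene_b)
  tl <- design_tiling(ia[3, ], ib[1, ], gen$genome, 56, 10)
  for (id in c("x", "y")) {
    al <- mat$alleles[[id]]
    sc <- scan_breakpoint(al, tl, gen$genome)
    expect_gt(nrow(sc$pairs), 0)
    j <- al$event$breakpoint_a + 1L   # allele position of the junction
    expect_lte(sc$breakpoint_interval[1], j)
    expect_gte(sc$breakpoint_interval[2], j)
    # fusion specificity: no reported pair amplifies either wild type
    for (i in seq_len(min(nrow(sc$pairs), 5))) {
      fw <- tl$forward[tl$forward$name == sc$pairs$forward[i], ]
      rv <- tl$reverse[tl$reverse$name == sc$pairs$reverse[i], ]
      for (ct in names(gen$genome)) {
        expect_equal(nrow(ispcr(gen$genome[[ct]],
                                primer(fw$name, fw$sequence),
                                primer(rv$name, rv$sequence),
                                max_product = 3000)), 0L)
      }
    }
  }
  # a wild-type "allele" built from the same contig fires nothing
  ev <- gen$truth$events[[1]]
  fake <- mat$alleles[["x"]]
  fake$sequence <- gen$genome[["contigA"]]
  expect_equal(nrow(scan_breakpoint(fake, tl, gen$genome)$pairs), 0L)
})

test_that("narrower tiling never widens the implied interval", {
  gen <- preset_gen()
  mat <- generate_fusion_materials(gen)
  ia <- introns_of(gen$gene_a); ib <- introns_of(gen$gene_b)
  al <- mat$alleles[["x"]]
  coarse <- scan_breakpoint(al, design_tiling(ia[3, ], ib[1, ],
                                              gen$genome, 14, 5), gen$genome)
  fine <- scan_breakpoint(al, design_tiling(ia[3, ], ib[1, ],
                                            gen$genome, 56, 10), gen$genome)
  expect_lte(diff(fine$breakpoint_interval),
             diff(coarse$breakpoint_interval))
})

test_that("primer validation and TSV round trip", {
  expect_error(primer("p", "ACGTACGT"), ">= 15")
  expect_error(primer("p", "ACGTACGTACGTACGTN"), "ACGT")
  ps <- list(primer("A", "ACGTACGTACGTACGTAC"),
             primer("B", "TTGCATTGCATTGCAGGC"))
  f <- tempfile(fileext = ".tsv")
  write_primers(ps, f)
  back <- read_primers(f)
  expect_equal(vapply(back, `[[`, character(1), "sequence"),
               vapply(ps, `[[`, character(1), "sequence"))
})
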