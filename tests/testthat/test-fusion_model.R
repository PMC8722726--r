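# spec for round-trip experiments: roomy introns so several events fit
roundtrip_spec <- function(seed, events) {
  synthetic_spec(
    seed = seed,
    gene_a = list(id = "gA", exon_lengths = c(100, 100, 100),
                  intron_lengths = c(200, 2500)),
    gene_b = list(id = "gB", exon_lengths = c(100, 100),
                  intron_lengths = c(2000)),
    stem = NULL, events = events, read_length = 400, n_reads = 1)
}

test_that("allele sequence and length follow the join identity", {
  set.seed(61)
  genome <- c(cA = rnd_dna(600), cB = rnd_dna(600))
  ga <- gene_model("gA", "cA", "+",
                   data.frame(start = c(50, 300), end = c(150, 400)))
  gb <- gene_model("gB", "cB", "+",
                   data.frame(start = c(50, 300), end = c(150, 400)))
  for (ins in c("", "AA", "GCGTT")) {
    ev <- fusion_event("e", "gA", "gB", 200, 250, insertion = ins)
    al <- make_fusion_allele(genome, ga, gb, ev)
    expect_equal(nchar(al$sequence),
                 (200 + 1) + nchar(ins) + (600 - 250))
    expect_identical(al$sequence,
                     paste0(substr(genome[["cA"]], 1, 201), ins,
                            substr(genome[["cB"]], 251, 600)))
    expect_equal(al$new_intron$start, 150)
    expect_equal(al$new_intron$end, 300 + (201 + nchar(ins) - 250))
  }
  # exonic breakpoints are outside the modeled class
  expect_error(make_fusion_allele(genome, ga, gb,
                                  fusion_event("e", "gA", "gB", 100, 250)),
               "not intronic")
  expect_error(make_fusion_allele(genome, ga, gb,
                                  fusion_event("e", "gA", "gB", 200, 320)),
               "not intronic")
})

test_that("JAZF1/SUZ12-like breakpoints keep exons 1-3 and 2-16, junction 3->2", {
  gen <- preset_gen()
  mat <- generate_fusion_materials(gen)
  al <- mat$alleles[["x"]]
  expect_equal(sum(al$exons$gene == "geneA"), 3L)
  expect_equal(sum(al$exons$gene == "geneB"), 15L)
  tx <- splice_fusion_transcript(al)
  expect_equal(unname(tx$junction), c(3L, 2L))
  # mature length equals the sum of retained exon lengths
  ea <- gen$gene_a$exons; eb <- gen$gene_b$exons
  expect_equal(nchar(tx$mature_sequence),
               sum((ea$end - ea$start)[1:3]) + sum((eb$end - eb$start)[2:16]))
  # junction position lies exactly at the annotated exon boundary
  expect_equal(tx$junction_pos, sum((ea$end - ea$start)[1:3]))
})

test_that("first-intron breakpoints give the boundary junction (1 -> 2)", {
  set.seed(71)
  genome <- c(cA = rnd_dna(700), cB = rnd_dna(700))
  ex <- data.frame(start = c(50, 300, 550), end = c(150, 400, 650))
  ga <- gene_model("gA", "cA", "+", ex)
  gb <- gene_model("gB", "cB", "+", ex)
  al <- make_fusion_allele(genome, ga, gb,
                           fusion_event("e", "gA", "gB", 200, 250))
  tx <- splice_fusion_transcript(al)
  expect_equal(unname(tx$junction), c(1L, 2L))
  # losing all exons on one side refuses to splice
  al2 <- al
  al2$exons <- al2$exons[al2$exons$gene != "gA", ]
  expect_error(splice_fusion_transcript(al2), "cannot splice")
})

test_that("clean junctions and untemplated insertions are recovered exactly", {
  gen <- preset_gen()
  mat <- generate_fusion_materials(gen)
  sa <- gen$genome[["contigA"]]; sb <- gen$genome[["contigB"]]
  truth <- list(x = gen$truth$events[[1]], y = gen$truth$events[[2]])
  for (nm in names(mat$reads)) {
    ev_id <- sub("read_([xy])_.*", "\\1", nm)
    inf <- infer_breakpoint(mat$reads[[nm]], sa, sb)
    expect_equal(inf$status, "ok")
    expect_equal(inf$event$breakpoint_a, truth[[ev_id]]$breakpoint_a)
    expect_equal(inf$event$breakpoint_b, truth[[ev_id]]$breakpoint_b)
    expect_identical(inf$event$insertion, truth[[ev_id]]$insertion)
    expect_equal(inf$event$microhomology_length, 0L)
    expect_equal(inf$mismatches, 0L)
  }
  # the "y" junction carries the 2-nt untemplated insertion
  inf_y <- infer_breakpoint(mat$reads[["read_y_1"]], sa, sb)
  expect_identical(inf_y$event$insertion, "AA")
  expect_equal(nchar(inf_y$event$insertion), 2L)
})

test_that("inference agrees with the exhaustive split oracle on short reads", {
  set.seed(83)
  spec <- roundtrip_spec(301, list(
    list(id = "e1", intron_a = 2, offset_a = 700, intron_b = 1,
         offset_b = 600, insertion = "", microhomology = 0),
    list(id = "e2", intron_a = 2, offset_a = 1400, intron_b = 1,
         offset_b = 1100, insertion = "TTGAC", microhomology = 0),
    list(id = "e3", intron_a = 2, offset_a = 2000, intron_b = 1,
         offset_b = 300, insertion = "", microhomology = 3)))
  gen <- generate_genome(spec)
  mat <- generate_fusion_materials(gen)
  sa <- gen$genome[["contigA"]]; sb <- gen$genome[["contigB"]]
  for (ev in gen$truth$events) {
    al <- mat$alleles[[ev$event_id]]
    j <- ev$breakpoint_a + 1L
    for (lead in c(150, 120, 180)) {
      read <- substr(al$sequence, j - lead, j - lead + 299)  # 300 nt
      inf <- infer_breakpoint(read, sa, sb)
      want <- split_oracle(read, sa, sb)
      expect_equal(inf$status, "ok")
      expect_identical(inf$event$insertion, want$insertion)
      expect_equal(inf$event$microhomology_length, want$microhomology)
    }
  }
})

test_that("50 seeded random planted events invert exactly", {
  set.seed(907)
  n_done <- 0
  for (batch in 1:10) {
    events <- list()
    for (k in 1:5) {
      ins_len <- sample(0:10, 1)
      mh <- if (ins_len == 0) sample(0:6, 1) else 0L
      ins <- if (ins_len > 0)
        paste(sample(c("A", "C", "G", "T"), ins_len, TRUE), collapse = "")
      else ""
      events[[k]] <- list(id = paste0("e", k),
                          intron_a = 2, offset_a = 150 + (k - 1) * 460 +
                            sample(0:100, 1),
                          intron_b = 1, offset_b = 120 + (k - 1) * 360 +
                            sample(0:80, 1),
                          insertion = ins, microhomology = mh)
    }
    gen <- generate_genome(roundtrip_spec(1000 + batch, events))
    mat <- generate_fusion_materials(gen)
    sa <- gen$genome[["contigA"]]; sb <- gen$genome[["contigB"]]
    for (ev in gen$truth$events) {
      rd <- mat$reads[[paste0("read_", ev$event_id, "_1")]]
      inf <- infer_breakpoint(rd, sa, sb)
      expect_equal(inf$status, "ok")
      expect_equal(inf$event$breakpoint_a, ev$breakpoint_a)
      expect_equal(inf$event$breakpoint_b, ev$breakpoint_b)
      expect_identical(inf$event$insertion, ev$insertion)
      expect_equal(inf$event$microhomology_length, ev$microhomology_length)
      # ambiguity window has microhomology + 1 placements
      expect_equal(diff(inf$ambiguity) + 1L,
                   ev$microhomology_length + 1L)
      n_done <- n_done + 1
    }
  }
  expect_equal(n_done, 50)
})

test_that("unanchorable reads are unmappable, not an error", {
  gen <- preset_gen()
  sa <- gen$genome[["contigA"]]; sb <- gen$genome[["contigB"]]
  expect_equal(infer_breakpoint(rnd_dna(200, seed = 5), sa, sb)$status,
               "unmappable")
  expect_equal(infer_breakpoint("ACGTACGT", sa, sb)$status, "unmappable")
})

test_that("microhomology_at matches the allele-shift oracle", {
  set.seed(121)
  for (k in 1:12) {
    mh_planted <- sample(0:6, 1)
    spec <- roundtrip_spec(2000 + k, list(
      list(id = "e", intron_a = 2, offset_a = 900 + sample(0:400, 1),
           intron_b = 1, offset_b = 700 + sample(0:300, 1),
           insertion = "", microhomology = mh_planted)))
    gen <- generate_genome(spec)
    ev <- gen$truth$events[[1]]
    sa <- gen$genome[["contigA"]]; sb <- gen$genome[["contigB"]]
    got <- microhomology_at(ev, sa, sb)
    expect_equal(got, mh_planted)
    expect_equal(got, mh_oracle(ev, sa, sb))
  }
})

test_that("event tables honour the coordinate convention parameter", {
  gen <- preset_gen()
  ev <- gen$truth$events[[1]]
  t1 <- fusion_event_table(list(ev), gen$gene_a, gen$gene_b)
  t2 <- fusion_event_table(list(ev), gen$gene_a, gen$gene_b,
                           convention = "first_lost")
  expect_equal(t1$pos_a, ev$breakpoint_a + 1L)
  expect_equal(t2$pos_a, ev$breakpoint_a + 2L)
  expect_equal(t1$pos_b, ev$breakpoint_b + 1L)
  expect_equal(t2$pos_b, ev$breakpoint_b)
  expect_error(fusion_event("bad", "a", "b", 1, 2, insertion = "AA",
                            microhomology_length = 2),
               "mutually exclusive")
})
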