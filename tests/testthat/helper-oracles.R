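# Independent brute-force oracles.  These reimplement the contracts
# checked by the production code from scratch (pure R, no shared
# helpers beyond base string ops) so that agreement is meaningful.

# affine-gap local alignment, O(n*m) dynamic program; returns the
# optimal score and the first-encountered (row-major) optimal end cell
sw_oracle <- function(a, b, match = 2, mismatch = -3, go = 5, ge = 2) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  Hprev <- numeric(m + 1); Fprev <- rep(-Inf, m + 1)
  best <- list(score = 0, a_end = 0L, b_end = 0L)
  for (i in seq_len(n)) {
    Hcur <- numeric(m + 1); Fcur <- rep(-Inf, m + 1)
    E <- -Inf
    for (j in seq_len(m)) {
      E <- max(Hcur[j] - go - ge, E - ge)
      Fcur[j + 1] <- max(Hprev[j + 1] - go - ge, Fprev[j + 1] - ge)
      s <- if (av[i] == "N" || bv[j] == "N") mismatch
           else if (av[i] == bv[j]) match else mismatch
      h <- max(0, Hprev[j] + s, E, Fcur[j + 1])
      Hcur[j + 1] <- h
      if (h > best$score) best <- list(score = h, a_end = i, b_end = j)
    }
    Hprev <- Hcur; Fprev <- Fcur
  }
  best
}

# quadratic sliding-window in-silico PCR: returns sorted (start, end)
# product table under the same binding rules as the production engine
naive_ispcr <- function(template, fwd, rev, max_product = 5000,
                        max_mismatch = 0) {
  n <- nchar(template)
  mism <- function(site, p) {
    sv <- strsplit(site, "", fixed = TRUE)[[1]]
    pv <- strsplit(p, "", fixed = TRUE)[[1]]
    sum(sv != pv | sv == "N")
  }
  sites <- function(p, pent_at) {
    lp <- nchar(p)
    hits <- integer(0)
    if (n < lp) return(hits)
    for (s in 0:(n - lp)) {
      site <- substr(template, s + 1, s + lp)
      if (mism(site, p) > max_mismatch) next
      pent_ok <- if (pent_at == "right")
        substr(site, lp - 4, lp) == substr(p, lp - 4, lp)
      else substr(site, 1, 5) == substr(p, 1, 5)
      if (pent_ok) hits <- c(hits, s)
    }
    hits
  }
  rc <- function(x) paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "",
                                       fixed = TRUE)[[1]]), collapse = "")
  fs <- sites(fwd, "right")
  rs <- sites(rc(rev), "left")
  out <- NULL
  lf <- nchar(fwd); lr <- nchar(rev)
  for (f in fs) for (r in rs) {
    if (r < f + lf) next
    if (r + lr - f > max_product) next
    out <- rbind(out, data.frame(start = f, end = r + lr))
  }
  if (is.null(out)) return(data.frame(start = integer(0), end = integer(0)))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive split-point search for a junction read: largest exact
# A-prefix and B-suffix, classified like the production inference
split_oracle <- function(read, A, B) {
  L <- nchar(read)
  iA <- 0L
  for (i in seq_len(L)) {
    if (grepl(substr(read, 1, i), A, fixed = TRUE)) iA <- i else break
  }
  jB <- L + 1L
  for (j in rev(seq_len(L))) {
    if (grepl(substr(read, j, L), B, fixed = TRUE)) jB <- j else break
  }
  if (jB > iA + 1L) {
    list(insertion = substr(read, iA + 1L, jB - 1L), microhomology = 0L,
         matched = iA + (L - jB + 1L))
  } else {
    list(insertion = "", microhomology = iA - jB + 1L,
         matched = iA + (L - jB + 1L))
  }
}

# count the junction-placement ambiguity of an event by shifting the
# breakpoint and comparing the resulting allele sequences
mh_oracle <- function(event, A, B, max_shift = 20) {
  build <- function(bpA, bpB) {
    paste0(substr(A, 1, bpA + 1), event$insertion,
           substr(B, bpB + 1, nchar(B)))
  }
  ref <- build(event$breakpoint_a, event$breakpoint_b)
  ok <- 0L
  for (d in seq_len(max_shift)) {   # shift junction left
    if (build(event$breakpoint_a - d, event$breakpoint_b - d) == ref)
      ok <- ok + 1L else break
  }
  for (d in seq_len(max_shift)) {   # shift junction right
    if (build(event$breakpoint_a + d, event$breakpoint_b + d) == ref)
      ok <- ok + 1L else break
  }
  ok
}

# independent FASTA record counter (line scanner)
count_fasta_records <- function(path) {
  sum(startsWith(readLines(path, warn = FALSE), ">"))
}

rc_chr <- function(x) paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "",
                                         fixed = TRUE)[[1]]), collapse = "")
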