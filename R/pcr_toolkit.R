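## pcr_toolkit: in-silico PCR, nested amplification schemes, and
## multiplex tiling primer design for genomic breakpoint scanning.
##
## The binding model is pure sequence matching: a primer binds where it
## matches with at most `max_mismatch` mismatches AND its 3'-terminal
## five bases match exactly.  No melting-temperature thermodynamics.

#' Construct a primer
#'
#' @param name primer label (e.g. `"A"`, `"3F2"`).
#' @param sequence 5'->3' nucleotide string, length >= 15, alphabet
#'   ACGT.
#' @return an object of class `primer`.
#' @export
primer <- function(name, sequence) {
  if (!is.character(sequence) || nchar(sequence) < 15L)
    stop("primer must be >= 15 nt", call. = FALSE)
  if (grepl("[^ACGT]", sequence))
    stop("primer alphabet is ACGT", call. = FALSE)
  structure(list(name = name, sequence = sequence), class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer> %s  5'-%s-3' (%d nt)\n", x$name, x$sequence,
              nchar(x$sequence)))
  invisible(x)
}

empty_amplicons <- function() {
  data.frame(template_id = character(0), start = integer(0),
             end = integer(0), length = integer(0),
             forward = character(0), reverse = character(0),
             sequence = character(0))
}

## 0-based start positions where `p` binds the plus strand of `s`
## (max_mismatch allowed outside the exact 3' pentamer).  `three_prime`
## is "right" for forward primers (pentamer at site end) and "left" for
## the reverse complement of a reverse primer (pentamer at site start).
primer_sites <- function(p, s, max_mismatch = 0L, three_prime = "right") {
  lp <- nchar(p)
  if (nchar(s) < lp) return(integer(0))
  hits <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(p), Biostrings::DNAString(s),
    max.mismatch = max_mismatch, with.indels = FALSE)) - 1L
  if (length(hits) == 0L || max_mismatch == 0L) return(hits)
  pent_p <- if (three_prime == "right") substr(p, lp - 4L, lp) else substr(p, 1L, 5L)
  ok <- vapply(hits, function(h) {
    site <- subseq0(s, h, h + lp)
    pent_s <- if (three_prime == "right") substr(site, lp - 4L, lp)
              else substr(site, 1L, 5L)
    pent_s == pent_p
  }, logical(1))
  hits[ok]
}

#' In-silico PCR
#'
#' Finds every product where `forward` matches the plus strand of the
#' template and `reverse` matches the minus strand downstream (i.e. the
#' reverse complement of `reverse` occurs on the plus strand), with
#' non-overlapping primer sites, product length at most `max_product`,
#' and the 3'-terminal five bases of each primer matching exactly
#' regardless of `max_mismatch`.
#'
#' @param template nucleotide string (or a single named element of a
#'   genome map).
#' @param forward,reverse [primer()] objects.
#' @param max_product maximum product length in bp.
#' @param max_mismatch mismatches tolerated outside the 3' pentamer.
#' @param template_id label for the report.
#' @return data.frame of amplicons (0-based half-open `start`/`end`,
#'   `length`, primer names, product `sequence`), sorted by start then
#'   end; empty when there is no product.
#' @export
ispcr <- function(template, forward, reverse, max_product = 5000L,
                  max_mismatch = 0L, template_id = "template") {
  stopifnot(inherits(forward, "primer"), inherits(reverse, "primer"))
  s <- as.character(template)[1]
  fs <- primer_sites(forward$sequence, s, max_mismatch, "right")
  if (length(fs) == 0L) return(empty_amplicons())
  rc <- revcomp(reverse$sequence)
  rs <- primer_sites(rc, s, max_mismatch, "left")
  if (length(rs) == 0L) return(empty_amplicons())
  lf <- nchar(forward$sequence); lr <- nchar(reverse$sequence)
  out <- list()
  for (f in fs) for (r in rs) {
    if (r < f + lf) next
    end <- r + lr
    len <- end - f
    if (len > max_product) next
    out[[length(out) + 1L]] <- data.frame(
      template_id = template_id, start = f, end = end, length = len,
      forward = forward$name, reverse = reverse$name,
      sequence = subseq0(s, f, end))
  }
  if (length(out) == 0L) return(empty_amplicons())
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Construct a nested-PCR scheme
#'
#' @param rounds list of rounds; each round is a list with elements
#'   `forward` (one [primer()] or a list of alternatives) and `reverse`
#'   (same).  A final round with two alternative forward primers
#'   reproduces the characteristic two-product band pattern.
#' @return an object of class `nested_scheme`.
#' @export
nested_scheme <- function(rounds) {
  norm <- function(x) if (inherits(x, "primer")) list(x) else x
  rounds <- lapply(rounds, function(r) {
    stopifnot(!is.null(r$forward), !is.null(r$reverse))
    list(forward = norm(r$forward), reverse = norm(r$reverse))
  })
  structure(list(rounds = rounds), class = "nested_scheme")
}

#' Run a nested-PCR scheme
#'
#' Round `r` runs [ispcr()] with every forward x reverse combination on
#' every product of round `r - 1`; an empty round propagates as empty
#' downstream (no error).  Coordinates are tracked back to the root
#' template (`root_start`/`root_end`).
#'
#' @param template root template string.
#' @param scheme a [nested_scheme()].
#' @param max_product,max_mismatch per-round [ispcr()] settings.
#' @param template_id label for the root template.
#' @return list with one amplicon data.frame per round.
#' @export
nested_pcr <- function(template, scheme, max_product = 5000L,
                       max_mismatch = 0L, template_id = "template") {
  stopifnot(inherits(scheme, "nested_scheme"))
  templates <- data.frame(id = template_id, seq = as.character(template)[1],
                          offset = 0L)
  out <- list()
  for (r in seq_along(scheme$rounds)) {
    rd <- scheme$rounds[[r]]
    prods <- list()
    for (t in seq_len(nrow(templates))) {
      for (fw in rd$forward) for (rv in rd$reverse) {
        am <- ispcr(templates$seq[t], fw, rv, max_product, max_mismatch,
                    template_id = templates$id[t])
        if (nrow(am) > 0L) {
          am$root_start <- am$start + templates$offset[t]
          am$root_end <- am$end + templates$offset[t]
          prods[[length(prods) + 1L]] <- am
        }
      }
    }
    round_df <- if (length(prods) > 0L) do.call(rbind, prods) else {
      cbind(empty_amplicons(), root_start = integer(0), root_end = integer(0))
    }
    if (nrow(round_df) > 0L) {
      round_df <- round_df[!duplicated(round_df[c("root_start", "root_end",
                                                  "forward", "reverse")]), ]
      round_df <- round_df[order(round_df$root_start, round_df$root_end), ]
      rownames(round_df) <- NULL
    }
    out[[r]] <- round_df
    templates <- if (nrow(round_df) > 0L)
      data.frame(id = sprintf("round%d_%d", r, seq_len(nrow(round_df))),
                 seq = round_df$sequence, offset = round_df$root_start)
    else templates[0, ]
  }
  out
}

#' Design a multiplex tiling scheme across two introns
#'
#' Places `n_forward` forward 20-mer sites evenly across intron A and
#' `n_reverse` reverse sites across intron B (spacing = intron length
#' divided by count, rounded down; the last site is clamped to fit).
#' Every emitted site must be N-free and its k-mer unique in the union
#' of the two contigs (both strands); violating sites are shifted to
#' the nearest valid position.
#'
#' @param intron_a,intron_b [interval()]s (or one-row data.frames from
#'   [introns_of()]).
#' @param genome named character vector.
#' @param n_forward,n_reverse site counts (>= 1).
#' @param site_length primer site length (default 20).
#' @return an object of class `tiling_scheme`: list with `forward` and
#'   `reverse` data.frames (`name`, `contig_id`, `start`, `end`,
#'   `sequence` -- primer sequence 5'->3'), and the two spacings.
#' @export
design_tiling <- function(intron_a, intron_b, genome, n_forward, n_reverse,
                          site_length = 20L) {
  as_iv <- function(x) {
    if (is.data.frame(x)) interval(x$contig_id, x$start, x$end, x$strand)
    else x
  }
  intron_a <- as_iv(intron_a); intron_b <- as_iv(intron_b)
  if (n_forward < 1L || n_reverse < 1L)
    stop("site counts must be >= 1", call. = FALSE)
  contigs <- genome[unique(c(intron_a$contig_id, intron_b$contig_id))]

  site_ok <- function(intron, off) {
    iv <- sense_range_to_genomic(intron, off, off + site_length)
    seq <- sense_sequence(iv, genome)
    if (grepl("N", seq, fixed = TRUE)) return(NULL)
    if (count_occurrences(seq, contigs) != 1L) return(NULL)
    list(iv = iv, seq = seq)
  }
  lay_out <- function(intron, n, prefix, reverse = FALSE) {
    L <- iv_width(intron)
    if (L < site_length)
      stop("intron too short (", L, " nt) for ", site_length, "-nt sites",
           call. = FALSE)
    spacing <- L %/% n
    if (spacing < 1L)
      stop("intron too short (", L, " nt) for ", n, " sites", call. = FALSE)
    rows <- list()
    for (k in seq_len(n)) {
      off0 <- min((k - 1L) * spacing, L - site_length)
      hit <- NULL
      for (d in 0L:max(L, 1L)) {          # nearest valid position
        for (off in unique(c(off0 + d, off0 - d))) {
          if (off < 0L || off + site_length > L) next
          hit <- site_ok(intron, off)
          if (!is.null(hit)) break
        }
        if (!is.null(hit)) break
      }
      if (is.null(hit))
        stop("no valid unique ", site_length, "-mer site near offset ",
             off0, " of ", intron$contig_id, call. = FALSE)
      pseq <- if (reverse) revcomp(hit$seq) else hit$seq
      rows[[k]] <- data.frame(name = sprintf("%s%02d", prefix, k),
                              contig_id = hit$iv$contig_id,
                              start = hit$iv$start, end = hit$iv$end,
                              sequence = pseq)
    }
    df <- do.call(rbind, rows)
    df <- df[order(df$start), ]
    rownames(df) <- NULL
    list(df = df, spacing = spacing)
  }
  fwd <- lay_out(intron_a, n_forward, "F", reverse = FALSE)
  rev <- lay_out(intron_b, n_reverse, "R", reverse = TRUE)
  structure(list(forward = fwd$df, reverse = rev$df,
                 spacing_a = fwd$spacing, spacing_b = rev$spacing,
                 site_length = as.integer(site_length)),
            class = "tiling_scheme")
}

#' @export
print.tiling_scheme <- function(x, ...) {
  cat(sprintf("<tiling_scheme> %d forward (spacing %d) x %d reverse (spacing %d), %d-nt sites\n",
              nrow(x$forward), x$spacing_a, nrow(x$reverse), x$spacing_b,
              x$site_length))
  invisible(x)
}

#' Scan a fusion allele for the breakpoint with a tiling scheme
#'
#' Evaluates every forward x reverse tiling pair independently (the
#' multiplex model) on the fused allele and on both wild-type contigs.
#' A pair is fusion-specific when it amplifies the allele but yields no
#' product on either wild-type locus.  The implied breakpoint interval
#' (allele coordinates between the innermost firing pair's primer
#' sites) is reported.
#'
#' @param allele a [make_fusion_allele()] result.
#' @param tiling a [design_tiling()] scheme.
#' @param genome wild-type genome map (both contigs).
#' @param max_product maximum product length considered.
#' @return list with `pairs` (data.frame of fusion-specific pairs and
#'   their allele amplicons) and `breakpoint_interval` (0-based
#'   half-open allele coordinates bracketing the junction; `NULL` when
#'   nothing fired).
#' @export
scan_breakpoint <- function(allele, tiling, genome, max_product = 3000L) {
  stopifnot(inherits(allele, "fusion_allele"),
            inherits(tiling, "tiling_scheme"))
  templates <- c(list(allele = allele$sequence), as.list(genome))
  slen <- tiling$site_length
  ## binding sites per template, computed once per primer
  fsites <- lapply(templates, function(s)
    lapply(tiling$forward$sequence, function(p)
      primer_sites(p, s, 0L, "right")))
  rsites <- lapply(templates, function(s)
    lapply(tiling$reverse$sequence, function(p)
      primer_sites(revcomp(p), s, 0L, "left")))
  fires <- function(tpl, fi, ri) {
    fs <- fsites[[tpl]][[fi]]; rs <- rsites[[tpl]][[ri]]
    if (length(fs) == 0L || length(rs) == 0L) return(NULL)
    for (f in fs) for (r in rs) {
      if (r >= f + slen && (r + slen - f) <= max_product)
        return(c(f, r + slen))
    }
    NULL
  }
  rows <- list()
  for (fi in seq_len(nrow(tiling$forward))) {
    for (ri in seq_len(nrow(tiling$reverse))) {
      amp <- fires("allele", fi, ri)
      if (is.null(amp)) next
      wt <- vapply(names(genome), function(g)
        !is.null(fires(g, fi, ri)), logical(1))
      if (any(wt)) next
      rows[[length(rows) + 1L]] <- data.frame(
        forward = tiling$forward$name[fi],
        reverse = tiling$reverse$name[ri],
        start = amp[1], end = amp[2], length = amp[2] - amp[1],
        fwd_site_end = amp[1] + slen, rev_site_start = amp[2] - slen)
    }
  }
  if (length(rows) == 0L)
    return(list(pairs = data.frame(), breakpoint_interval = NULL))
  df <- do.call(rbind, rows)
  df <- df[order(df$length), ]
  rownames(df) <- NULL
  list(pairs = df,
       breakpoint_interval = c(max(df$fwd_site_end), min(df$rev_site_start)))
}

#' Read primers from a TSV file
#'
#' Two columns, `name` and `sequence` (header optional).
#'
#' @param path TSV file.
#' @return list of [primer()] objects.
#' @export
read_primers <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("name", "sequence"),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L && toupper(df$sequence[1]) == "SEQUENCE")
    df <- df[-1L, , drop = FALSE]
  lapply(seq_len(nrow(df)), function(k) primer(df$name[k],
                                               toupper(df$sequence[k])))
}

#' Write primers to a TSV file
#'
#' @param primers list of [primer()] objects (or a `tiling_scheme`,
#'   whose forward and reverse primers are both written).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_primers <- function(primers, path) {
  if (inherits(primers, "tiling_scheme")) {
    df <- rbind(primers$forward[c("name", "sequence")],
                primers$reverse[c("name", "sequence")])
  } else {
    df <- data.frame(name = vapply(primers, `[[`, character(1), "name"),
                     sequence = vapply(primers, `[[`, character(1), "sequence"))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
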