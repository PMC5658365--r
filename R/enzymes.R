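#' Restriction enzyme definitions and site finding
#'
#' The enzyme registry ships canonical REBASE-style cut geometries as data in
#' `inst/extdata/enzymes.tsv` (human-editable: name, recognition, cut_top,
#' cut_bottom, kind).  `cut_top`/`cut_bottom` are offsets in nucleotides from
#' the 3' end of the recognition site to the top-/bottom-strand cut; negative
#' offsets place the cut inside the site (type IIP).  The overhang length is
#' `cut_bottom - cut_top`: positive = 5' overhang, negative = 3' overhang,
#' zero = blunt.
#'
#' @name enzyme_kit
NULL

.sevaforge_env <- new.env(parent = emptyenv())

load_enzyme_table <- function() {
  if (!is.null(.sevaforge_env$enzymes)) return(.sevaforge_env$enzymes)
  path <- system.file("extdata", "enzymes.tsv", package = "sevaforge")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "recognition", "cut_top", "cut_bottom", "kind") %in% names(tab)))
  .sevaforge_env$enzymes <- tab
  tab
}

#' Look up an enzyme by name
#' @param name enzyme name, e.g. `"BsaI"`.
#' @return an object of class `enzyme` with fields `name`, `recognition`,
#'   `cut_top`, `cut_bottom`, `kind`.
#' @export
enzyme <- function(name) {
  if (inherits(name, "enzyme")) return(name)
  tab <- load_enzyme_table()
  i <- match(name, tab$name)
  if (is.na(i)) stop(sprintf("unknown enzyme name: '%s'", name))
  e <- as.list(tab[i, ])
  structure(e, class = "enzyme")
}

#' @export
print.enzyme <- function(x, ...) {
  cat(sprintf("<enzyme %s %s(%d/%d) %s>\n", x$name, x$recognition,
              x$cut_top, x$cut_bottom, x$kind))
  invisible(x)
}

#' List registered enzymes
#' @return data.frame of the enzyme registry, with derived `overhang_length`
#'   and `polarity` columns.
#' @export
list_enzymes <- function() {
  tab <- load_enzyme_table()
  ov <- tab$cut_bottom - tab$cut_top
  tab$overhang_length <- abs(ov)
  tab$polarity <- ifelse(ov > 0, "five_prime", ifelse(ov < 0, "three_prime", "blunt"))
  tab
}

#' Overhang polarity of an enzyme
#' @param e an [enzyme()] or name.
#' @export
enzyme_polarity <- function(e) {
  e <- enzyme(e)
  ov <- e$cut_bottom - e$cut_top
  if (ov > 0) "five_prime" else if (ov < 0) "three_prime" else "blunt"
}

iupac_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  ch <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  if (any(!ch %in% names(map))) stop("invalid IUPAC pattern")
  paste(map[ch], collapse = "")
}

# All (possibly overlapping) 0-based match starts of an IUPAC pattern in a
# plain ACGT subject string.
pattern_starts <- function(subject, pattern) {
  rx <- paste0("(?=", iupac_regex(pattern), ")")
  m <- gregexpr(rx, subject, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m) - 1L
}

#' Locate recognition/cut sites of an enzyme on a sequence
#'
#' Scans both strands for every occurrence of the recognition pattern and
#' derives the cut coordinates from the enzyme geometry.  On circular
#' sequences the scan crosses the origin (the sequence is scanned doubled and
#' hits deduplicated by `rec_start` modulo length) and cut coordinates are
#' reported modulo length.  On linear sequences, hits whose cut positions
#' fall off either end are reported with `cleavable = FALSE`.
#'
#' @param seq a [ds_seq()].
#' @param enz an [enzyme()] or enzyme name.
#' @return data.frame with columns `enzyme`, `strand`, `rec_start` (0-based
#'   position of the leftmost base of the recognition footprint on the
#'   forward strand), `cut_top_pos`, `cut_bottom_pos` (0-based forward-strand
#'   cut coordinates: the strand is severed immediately before that index)
#'   and `cleavable`.  Rows are ordered by ascending `rec_start`, `+` strand
#'   first on ties.
#' @export
find_sites <- function(seq, enz) {
  if (!inherits(seq, "ds_seq")) stop("`seq` must be a ds_seq")
  e <- enzyme(enz)
  n <- ds_length(seq)
  lrec <- nchar(e$recognition)
  circular <- seq$topology == "circular"
  subject <- if (circular) paste0(seq$bases, substr(seq$bases, 1L, min(n, lrec - 1L))) else seq$bases

  hit_rows <- list()
  fwd <- pattern_starts(subject, e$recognition)
  if (circular) fwd <- unique(fwd %% n)
  for (s in fwd) {
    ct <- s + lrec + e$cut_top
    cb <- s + lrec + e$cut_bottom
    hit_rows[[length(hit_rows) + 1L]] <- c(strand = "+", s = s, ct = ct, cb = cb)
  }
  rcpat <- dna_revcomp(e$recognition)
  # skip the duplicate scan for palindromic recognition sites: the reverse
  # occurrence is the same physical site
  if (rcpat != toupper(e$recognition)) {
    rev <- pattern_starts(subject, rcpat)
    if (circular) rev <- unique(rev %% n)
    for (s in rev) {
      ct <- s - e$cut_bottom
      cb <- s - e$cut_top
      hit_rows[[length(hit_rows) + 1L]] <- c(strand = "-", s = s, ct = ct, cb = cb)
    }
  }
  if (!length(hit_rows)) {
    return(data.frame(enzyme = character(), strand = character(),
                      rec_start = integer(), cut_top_pos = integer(),
                      cut_bottom_pos = integer(), cleavable = logical(),
                      stringsAsFactors = FALSE))
  }
  strand <- vapply(hit_rows, function(h) h[["strand"]], character(1))
  s <- as.integer(vapply(hit_rows, function(h) h[["s"]], character(1)))
  ct <- as.integer(vapply(hit_rows, function(h) h[["ct"]], character(1)))
  cb <- as.integer(vapply(hit_rows, function(h) h[["cb"]], character(1)))
  if (circular) {
    cleavable <- rep(TRUE, length(s))
    ct <- ((ct %% n) + n) %% n
    cb <- ((cb %% n) + n) %% n
  } else {
    cleavable <- pmin(ct, cb) >= 0L & pmax(ct, cb) <= n & (s + lrec) <= n
  }
  out <- data.frame(enzyme = e$name, strand = strand, rec_start = s,
                    cut_top_pos = ct, cut_bottom_pos = cb,
                    cleavable = cleavable, stringsAsFactors = FALSE)
  out <- out[order(out$rec_start, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Cut window of a site hit on the forward strand, un-wrapped (may exceed the
# sequence length on circular molecules; caller normalises).  Returns
# list(start, end, polarity) with start < end for sticky cuts.
site_cut_window <- function(hit, e, n, circular) {
  ct <- hit$cut_top_pos; cb <- hit$cut_bottom_pos
  pol <- enzyme_polarity(e)
  if (circular) {
    # re-derive unwrapped coordinates from rec_start so windows near the
    # origin stay contiguous
    lrec <- nchar(e$recognition)
    if (hit$strand == "+") {
      ct <- hit$rec_start + lrec + e$cut_top
      cb <- hit$rec_start + lrec + e$cut_bottom
    } else {
      ct <- hit$rec_start - e$cut_bottom
      cb <- hit$rec_start - e$cut_top
    }
  }
  list(start = min(ct, cb), end = max(ct, cb), polarity = pol)
}
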