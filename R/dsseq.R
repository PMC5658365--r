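#' Double-stranded DNA with typed ends
#'
#' `ds_seq()` is the central container of the package: an annotated
#' double-stranded DNA molecule, linear or circular.  The `bases` field holds
#' the forward (top) strand 5'->3' over the *full extent* of the duplex, i.e.
#' including any single-stranded overhang regions at the two ends of a linear
#' molecule.  Which strand is recessed at an end is described by an
#' [end_spec()].
#'
#' Coordinates are 0-based and half-open throughout the package; on circular
#' molecules arithmetic is modulo length.
#'
#' @param bases character scalar over the ACGT alphabet (case-insensitive;
#'   upper-cased on ingestion).
#' @param topology `"linear"` or `"circular"`.
#' @param left_end,right_end [end_spec()] objects; linear molecules only.
#' @param features `data.frame` with columns `label`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), 0-based half-open intervals on the forward
#'   strand.  `NULL` means no annotations.
#' @param id optional identifier carried through digestion as provenance.
#' @param role optional part role (e.g. `"destination"`), used by the
#'   assembly classifier.
#' @return an object of class `ds_seq`.
#' @export
ds_seq <- function(bases, topology = c("linear", "circular"),
                   left_end = end_spec("blunt"), right_end = end_spec("blunt"),
                   features = NULL, id = NULL, role = NULL) {
  topology <- match.arg(topology)
  bases <- toupper(as.character(bases))
  if (length(bases) != 1L || is.na(bases)) stop("`bases` must be a single string")
  if (nchar(bases) == 0L) stop("empty sequence")
  if (grepl("[^ACGT]", bases)) stop("sequence bases must be ACGT only")
  if (is.null(features)) features <- empty_features()
  features <- validate_features(features, nchar(bases))
  x <- structure(list(
    bases = bases, topology = topology,
    left_end = if (topology == "linear") left_end else NULL,
    right_end = if (topology == "linear") right_end else NULL,
    features = features, id = id, role = role, meta = list()
  ), class = "ds_seq")
  x
}

empty_features <- function() {
  data.frame(label = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

validate_features <- function(f, len) {
  stopifnot(is.data.frame(f), all(c("label", "start", "end", "strand") %in% names(f)))
  f <- f[, c("label", "start", "end", "strand")]
  f$start <- as.integer(f$start); f$end <- as.integer(f$end)
  if (nrow(f) && any(f$start < 0 | f$end > len | f$start >= f$end))
    stop("feature intervals must satisfy 0 <= start < end <= length")
  if (nrow(f) && !all(f$strand %in% c("+", "-")))
    stop("feature strand must be '+' or '-'")
  f
}

#' Typed end of a linear duplex
#'
#' @param polarity `"five_prime"`, `"three_prime"` or `"blunt"`.
#' @param overhang the protruding single strand, read 5'->3' on the
#'   protruding strand; empty iff blunt.  At most 10 nt.
#' @return an object of class `end_spec`.
#' @export
end_spec <- function(polarity = c("blunt", "five_prime", "three_prime"),
                     overhang = "") {
  polarity <- match.arg(polarity)
  overhang <- toupper(overhang)
  if (nchar(overhang) > 10) stop("overhang length must be <= 10")
  if ((polarity == "blunt") != (nchar(overhang) == 0L))
    stop("blunt iff empty overhang")
  structure(list(polarity = polarity, overhang = overhang), class = "end_spec")
}

#' @export
print.end_spec <- function(x, ...) {
  cat(sprintf("<end %s%s>\n", x$polarity,
              if (nzchar(x$overhang)) paste0(" ", x$overhang) else ""))
  invisible(x)
}

#' @export
print.ds_seq <- function(x, ...) {
  cat(sprintf("<ds_seq %s, %d bp%s>\n", x$topology, ds_length(x),
              if (!is.null(x$id)) paste0(", id=", x$id) else ""))
  if (x$topology == "linear")
    cat(sprintf("  ends: %s/%s | %s/%s\n",
                x$left_end$polarity, x$left_end$overhang,
                x$right_end$polarity, x$right_end$overhang))
  if (nrow(x$features))
    cat(sprintf("  features: %s\n",
                paste(utils::head(x$features$label, 8), collapse = ", ")))
  invisible(x)
}

#' Length of a ds_seq (full extent of the forward strand)
#' @param x a [ds_seq()].
#' @export
ds_length <- function(x) nchar(x$bases)

#' Reverse complement of a DNA string
#'
#' Handles IUPAC ambiguity codes (used in enzyme recognition patterns only).
#' @param x character vector of DNA strings.
#' @export
dna_revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Reverse complement of a ds_seq
#'
#' Features are remapped to the new coordinate frame and strand-flipped; the
#' two end specs of a linear molecule swap sides (overhang strings are
#' unchanged: an overhang read 5'->3' on its protruding strand is invariant
#' under flipping the molecule).
#' @param x a [ds_seq()].
#' @export
ds_revcomp <- function(x) {
  n <- ds_length(x)
  f <- x$features
  if (nrow(f)) {
    new_start <- n - f$end
    new_end <- n - f$start
    f$start <- new_start; f$end <- new_end
    f$strand <- ifelse(f$strand == "+", "-", "+")
    f <- f[order(f$start), , drop = FALSE]
    rownames(f) <- NULL
  }
  out <- x
  out$bases <- dna_revcomp(x$bases)
  out$features <- f
  if (x$topology == "linear") {
    out$left_end <- x$right_end
    out$right_end <- x$left_end
  }
  out
}

#' Rotate a circular ds_seq
#'
#' The new origin is placed at `offset` (0-based); features are remapped and
#' features that would wrap the new origin are split into two labelled
#' segments.
#' @param x circular [ds_seq()].
#' @param offset integer rotation, taken modulo length.
#' @export
ds_rotate <- function(x, offset) {
  if (x$topology != "circular") stop("ds_rotate() requires a circular sequence")
  n <- ds_length(x)
  offset <- ((as.integer(offset) %% n) + n) %% n
  if (offset == 0L) return(x)
  out <- x
  out$bases <- paste0(substr(x$bases, offset + 1L, n), substr(x$bases, 1L, offset))
  f <- x$features
  if (nrow(f)) {
    rows <- vector("list", nrow(f))
    for (i in seq_len(nrow(f))) {
      s <- (f$start[i] - offset) %% n
      e <- s + (f$end[i] - f$start[i])
      if (e <= n) {
        rows[[i]] <- data.frame(label = f$label[i], start = s, end = e,
                                strand = f$strand[i], stringsAsFactors = FALSE)
      } else {
        # feature wraps the new origin: keep as two labelled segments
        rows[[i]] <- data.frame(
          label = paste0(f$label[i], c(":seg1", ":seg2")),
          start = c(s, 0L), end = c(n, e - n),
          strand = f$strand[i], stringsAsFactors = FALSE)
      }
    }
    f <- do.call(rbind, rows)
    f <- merge_seg_features(f)
    f <- f[order(f$start), , drop = FALSE]
    rownames(f) <- NULL
  }
  out$features <- f
  out
}

# re-join features that an earlier rotation split into :seg1/:seg2 halves
# once the two halves become adjacent again
merge_seg_features <- function(f) {
  repeat {
    merged <- FALSE
    for (i in grep(":seg1$", f$label)) {
      base <- sub(":seg1$", "", f$label[i])
      j <- which(f$label == paste0(base, ":seg2") & f$strand == f$strand[i] &
                   f$start == f$end[i])
      if (length(j) == 1L) {
        f$end[i] <- f$end[j]
        f$label[i] <- base
        f <- f[-j, , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) return(f)
  }
}

# Lexicographically smallest rotation of a string (Booth's algorithm, O(n)).
smallest_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(s)
  ch <- strsplit(paste0(s, s), "", fixed = TRUE)[[1]] # 1-based; d0(i) = ch[i+1]
  f <- rep(-1L, 2L * n)                               # failure fn, 0-based via f[i+1]
  k <- 0L
  for (j in 1L:(2L * n - 1L)) {                       # j is a 0-based index
    sj <- ch[j + 1L]
    i <- f[j - k]                                     # f0(j-k-1)
    while (i != -1L && sj != ch[k + i + 2L]) {
      if (sj < ch[k + i + 2L]) k <- j - i - 1L
      i <- f[i + 1L]
    }
    if (sj != ch[k + i + 2L]) {                       # i == -1 here
      if (sj < ch[k + 1L]) k <- j
      f[j - k + 1L] <- -1L
    } else {
      f[j - k + 1L] <- i + 1L
    }
  }
  substr(paste0(s, s), k + 1L, k + n)
}

#' Canonical form of a circular sequence
#'
#' Product identity for circular molecules: the lexicographically smallest
#' rotation of the forward strand, compared against the smallest rotation of
#' the reverse complement, taking the smaller of the two.  Two circular
#' molecules are the same iff their canonical strings are equal.
#' @param x circular [ds_seq()] or a plain base string.
#' @return character scalar.
#' @export
ds_canonical <- function(x) {
  s <- if (inherits(x, "ds_seq")) x$bases else toupper(x)
  a <- smallest_rotation(s)
  b <- smallest_rotation(dna_revcomp(s))
  if (a <= b) a else b
}

# Slice [start, end) of the forward strand, wrapping the origin when circular.
ds_slice <- function(x, start, end) {
  n <- ds_length(x)
  if (x$topology == "circular") {
    start <- ((start %% n) + n) %% n
    len <- end - start
    if (len < 0) stop("invalid slice")
    d <- paste0(x$bases, x$bases)
    if (start + len > 2L * n) stop("slice longer than doubled sequence")
    substr(d, start + 1L, start + len)
  } else {
    if (start < 0 || end > n || start > end) stop("slice out of range")
    substr(x$bases, start + 1L, end)
  }
}

#' Annotate a feature interval on a ds_seq
#' @param x a [ds_seq()].
#' @param label feature label.
#' @param start,end 0-based half-open interval on the forward strand.
#' @param strand `"+"` or `"-"`.
#' @return the annotated [ds_seq()].
#' @export
add_feature <- function(x, label, start, end, strand = "+") {
  f <- rbind(x$features,
             data.frame(label = label, start = as.integer(start),
                        end = as.integer(end), strand = strand,
                        stringsAsFactors = FALSE))
  f <- f[order(f$start), , drop = FALSE]
  rownames(f) <- NULL
  x$features <- f
  x
}

feature_labels <- function(x) unique(x$features$label)

has_feature <- function(x, label) label %in% x$features$label
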