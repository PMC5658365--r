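#' Restriction digestion and ligation
#'
#' `digest()` cuts a linear or circular duplex into fragments with typed
#' sticky ends; `ligate_fragments()` and `circularize()` join compatible
#' ends back into larger molecules.  A fragment is itself a linear
#' [ds_seq()] whose `bases` cover the full extent of the duplex (overhang
#' regions included) and whose `left_end`/`right_end` record which strand
#' protrudes.
#'
#' @name digestion
NULL

#' Digest a sequence with one or more enzymes
#'
#' Cut windows of all enzymes are merged and must not overlap (two enzymes
#' cutting within each other's overhang is an "ambiguous digestion" error).
#' A circular input with n cut windows yields n fragments, a linear input
#' n+1; the two new ends at each junction carry complementary end specs.
#' Duplex length is conserved: the fragment extents overlap by the overhang
#' length at each junction, so the sum of fragment lengths minus one
#' overhang per junction equals the input length.
#'
#' @param seq a [ds_seq()].
#' @param enzymes list of [enzyme()] objects or names.
#' @return list of fragments (class `ds_seq`, linear), ordered by cut
#'   coordinate.  Each carries `meta$provenance` (source id, producing
#'   enzymes) and, if the input had no cleavable site, the input itself is
#'   returned as a single fragment with `meta$uncut = TRUE`.
#' @export
digest <- function(seq, enzymes) {
  if (!inherits(seq, "ds_seq")) stop("`seq` must be a ds_seq")
  if (inherits(enzymes, "enzyme") || is.character(enzymes) && length(enzymes) == 1L)
    enzymes <- list(enzymes)
  enzymes <- lapply(enzymes, enzyme)
  n <- ds_length(seq)
  circular <- seq$topology == "circular"

  wins <- list()
  for (e in enzymes) {
    hits <- find_sites(seq, e)
    hits <- hits[hits$cleavable, , drop = FALSE]
    for (i in seq_len(nrow(hits))) {
      w <- site_cut_window(hits[i, ], e, n, circular)
      wins[[length(wins) + 1L]] <- list(start = w$start, end = w$end,
                                        polarity = w$polarity, enzyme = e$name)
    }
  }
  if (!length(wins)) {
    frag <- seq
    frag$meta$uncut <- TRUE
    frag$meta$provenance <- list(source = seq$id, enzymes = character())
    return(list(frag))
  }

  if (circular) {
    starts <- vapply(wins, `[[`, numeric(1), "start")
    rot <- ((min(starts) %% n) + n) %% n
    work <- ds_rotate(seq, rot)
    for (i in seq_along(wins)) {
      wins[[i]]$start <- ((wins[[i]]$start - rot) %% n + n) %% n
      wins[[i]]$end <- wins[[i]]$start + (wins[[i]]$end - (starts[i]))
    }
    # recompute end from invariant width
  } else {
    work <- seq
  }
  widths <- vapply(wins, function(w) w$end - w$start, numeric(1))
  starts <- vapply(wins, `[[`, numeric(1), "start")
  ord <- order(starts)
  wins <- wins[ord]; starts <- starts[ord]; widths <- widths[ord]
  ends <- starts + widths

  # deduplicate identical windows (palindromic sites hit on both strands)
  keep <- !duplicated(paste(starts, ends))
  wins <- wins[keep]; starts <- starts[keep]; ends <- ends[keep]

  m <- length(wins)
  # overlap check (including circular wrap back onto the first window)
  for (i in seq_len(m)) {
    lim <- if (i < m) starts[i + 1L] else if (circular) n + starts[1L] else n
    if (ends[i] > lim)
      stop(sprintf("ambiguous digestion: cut windows overlap near positions %d and %d",
                   as.integer(starts[i]),
                   as.integer(if (i < m) starts[i + 1L] else starts[1L])))
  }

  frag_between <- function(a_idx, b_idx, wrap = FALSE) {
    # fragment spanning from window a to window b (its extent covers both
    # windows' overhang regions)
    a <- wins[[a_idx]]; b <- wins[[b_idx]]
    span_start <- a$start
    span_end <- if (wrap) b$end + n else b$end
    bases <- ds_slice(work, span_start, span_end)
    len <- nchar(bases)
    ka <- a$end - a$start; kb <- b$end - b$start
    left <- if (a$polarity == "blunt") end_spec("blunt") else
      if (a$polarity == "five_prime") end_spec("five_prime", substr(bases, 1L, ka)) else
        end_spec("three_prime", dna_revcomp(substr(bases, 1L, ka)))
    right <- if (b$polarity == "blunt") end_spec("blunt") else
      if (b$polarity == "five_prime") end_spec("five_prime", dna_revcomp(substr(bases, len - kb + 1L, len))) else
        end_spec("three_prime", substr(bases, len - kb + 1L, len))
    f <- subset_features(work, span_start, span_end, n, circular)
    frag <- ds_seq(bases, "linear", left, right, features = f,
                   id = seq$id, role = seq$role)
    frag$meta$provenance <- list(source = seq$id,
                                 enzymes = unique(c(a$enzyme, b$enzyme)),
                                 span = c(span_start, span_end))
    frag
  }

  frags <- list()
  if (circular) {
    for (i in seq_len(m)) {
      j <- if (i < m) i + 1L else 1L
      frags[[length(frags) + 1L]] <- frag_between(i, j, wrap = (i == m))
    }
  } else {
    # leading fragment [0, end of window 1)
    lead_bases <- substr(work$bases, 1L, ends[1])
    b <- wins[[1L]]; kb <- ends[1] - starts[1]
    right <- if (b$polarity == "blunt") end_spec("blunt") else
      if (b$polarity == "five_prime")
        end_spec("five_prime", dna_revcomp(substr(lead_bases, nchar(lead_bases) - kb + 1L, nchar(lead_bases)))) else
          end_spec("three_prime", substr(lead_bases, nchar(lead_bases) - kb + 1L, nchar(lead_bases)))
    lead <- ds_seq(lead_bases, "linear", work$left_end, right,
                   features = subset_features(work, 0L, ends[1], n, FALSE),
                   id = seq$id, role = seq$role)
    lead$meta$provenance <- list(source = seq$id, enzymes = b$enzyme,
                                 span = c(0L, ends[1]))
    frags[[1L]] <- lead
    if (m > 1L) for (i in seq_len(m - 1L)) frags[[length(frags) + 1L]] <- frag_between(i, i + 1L)
    # trailing fragment [start of last window, n)
    a <- wins[[m]]; ka <- ends[m] - starts[m]
    tail_bases <- substr(work$bases, starts[m] + 1L, n)
    left <- if (a$polarity == "blunt") end_spec("blunt") else
      if (a$polarity == "five_prime") end_spec("five_prime", substr(tail_bases, 1L, ka)) else
        end_spec("three_prime", dna_revcomp(substr(tail_bases, 1L, ka)))
    tail <- ds_seq(tail_bases, "linear", left, work$right_end,
                   features = subset_features(work, starts[m], n, n, FALSE),
                   id = seq$id, role = seq$role)
    tail$meta$provenance <- list(source = seq$id, enzymes = a$enzyme,
                                 span = c(starts[m], n))
    frags[[length(frags) + 1L]] <- tail
  }
  frags
}

# Features of `work` fully contained in [start, end) (end may exceed n for a
# circular wrap; containment is then checked in the unrolled frame).
subset_features <- function(work, start, end, n, circular) {
  f <- work$features
  if (!nrow(f)) return(empty_features())
  if (circular && end > n) {
    # unrolled frame: features entirely in [start, n) or in [0, end - n)
    in1 <- f$start >= start & f$end <= n
    in2 <- f$end <= (end - n)
    res <- f[in1, , drop = FALSE]
    res$start <- res$start - start; res$end <- res$end - start
    res2 <- f[in2, , drop = FALSE]
    res2$start <- res2$start + (n - start); res2$end <- res2$end + (n - start)
    res <- rbind(res, res2)
  } else {
    keep <- f$start >= start & f$end <= end
    res <- f[keep, , drop = FALSE]
    res$start <- res$start - start; res$end <- res$end - start
  }
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Are two fragment ends ligatable?
#'
#' `a_end` is the right end of the upstream fragment, `b_end` the left end
#' of the downstream fragment.  Two sticky ends of equal polarity are
#' compatible iff one's protruding strand is the reverse complement of the
#' other's; blunt ends are compatible with blunt ends.  Mismatched-overhang
#' ligation is never allowed.
#'
#' @param a_end,b_end [end_spec()] objects.
#' @return logical scalar.
#' @export
ends_compatible <- function(a_end, b_end) {
  if (a_end$polarity != b_end$polarity) return(FALSE)
  if (a_end$polarity == "blunt") return(TRUE)
  if (nchar(a_end$overhang) != nchar(b_end$overhang)) return(FALSE)
  a_end$overhang == dna_revcomp(b_end$overhang)
}

#' Join two fragments at compatible ends
#'
#' Concatenates the duplexes (the annealed overhang region is counted once)
#' and records a `junction` feature spanning the scar so that loss or
#' persistence of recognition sites at the joint can be checked with
#' [find_sites()].
#'
#' @param a,b linear [ds_seq()] fragments; `a`'s right end is joined to
#'   `b`'s left end.
#' @return linear [ds_seq()].
#' @export
ligate_fragments <- function(a, b) {
  if (a$topology != "linear" || b$topology != "linear")
    stop("can only ligate linear fragments")
  if (a$right_end$polarity != b$left_end$polarity)
    stop("polarity mismatch between ends")
  if (nchar(a$right_end$overhang) != nchar(b$left_end$overhang))
    stop("overhang length mismatch between ends")
  if (!ends_compatible(a$right_end, b$left_end))
    stop("incompatible overhangs: ", a$right_end$overhang, " / ", b$left_end$overhang)
  k <- nchar(a$right_end$overhang)
  na <- ds_length(a)
  bases <- paste0(a$bases, substr(b$bases, k + 1L, ds_length(b)))
  fb <- b$features
  if (nrow(fb)) { fb$start <- fb$start + (na - k); fb$end <- fb$end + (na - k) }
  feats <- rbind(a$features, fb)
  out <- ds_seq(bases, "linear", a$left_end, b$right_end,
                features = feats, id = a$id, role = a$role)
  if (k > 0) out <- add_feature(out, "junction", na - k, na)
  out$meta$members <- c(frag_members(a), frag_members(b))
  out
}

frag_members <- function(x) {
  if (!is.null(x$meta$members)) x$meta$members else
    list(list(id = x$id, role = x$role, provenance = x$meta$provenance))
}

#' Circularize a fragment whose two ends are mutually compatible
#' @param frag linear [ds_seq()].
#' @return circular [ds_seq()].
#' @export
circularize <- function(frag) {
  if (frag$topology != "linear") stop("already circular")
  if (!ends_compatible(frag$right_end, frag$left_end))
    stop("fragment ends are not mutually compatible")
  k <- nchar(frag$right_end$overhang)
  n <- ds_length(frag)
  bases <- substr(frag$bases, 1L, n - k)
  f <- frag$features
  if (nrow(f)) f <- f[f$end <= n - k, , drop = FALSE]
  out <- ds_seq(bases, "circular", features = f, id = frag$id, role = frag$role)
  if (k > 0) out <- add_feature(out, "junction", 0L, k)
  out$meta$members <- frag_members(frag)
  out
}
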