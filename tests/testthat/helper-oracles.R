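# Independent brute-force oracles used across the suite.  These deliberately
# re-derive everything from first principles (per-offset scans, factorial
# enumeration, plain string surgery) and share no code path with the package
# internals they check.

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

# test a concrete window against an IUPAC pattern, character by character
oracle_match_at <- function(chars, pat_chars, offset) {
  for (k in seq_along(pat_chars)) {
    if (!chars[offset + k] %in% oracle_iupac[[pat_chars[k]]]) return(FALSE)
  }
  TRUE
}

# exhaustive scan of every offset on both strands; returns a data.frame of
# (strand, rec_start) with independently derived cut coordinates
oracle_scan <- function(bases, pattern, cut_top, cut_bottom,
                        topology = "linear") {
  n <- nchar(bases)
  lp <- nchar(pattern)
  subj <- if (topology == "circular") paste0(bases, bases) else bases
  chars <- strsplit(subj, "")[[1]]
  pc_f <- strsplit(toupper(pattern), "")[[1]]
  pc_r <- strsplit(oracle_revcomp_pattern(pattern), "")[[1]]
  lim <- if (topology == "circular") n else n - lp + 1L
  rows <- list()
  for (off in seq_len(max(lim, 0L))) {     # off is 1-based window start
    s <- off - 1L                          # 0-based
    if (off + lp - 1L <= length(chars) && oracle_match_at(chars, pc_f, s)) {
      ct <- s + lp + cut_top; cb <- s + lp + cut_bottom
      rows[[length(rows) + 1L]] <- data.frame(strand = "+", rec_start = s,
                                              ct = ct, cb = cb)
    }
    palindrome <- identical(pc_f, pc_r)
    if (!palindrome && off + lp - 1L <= length(chars) &&
        oracle_match_at(chars, pc_r, s)) {
      ct <- s - cut_bottom; cb <- s - cut_top
      rows[[length(rows) + 1L]] <- data.frame(strand = "-", rec_start = s,
                                              ct = ct, cb = cb)
    }
  }
  if (!length(rows)) return(data.frame(strand = character(),
                                       rec_start = integer(),
                                       ct = integer(), cb = integer()))
  out <- do.call(rbind, rows)
  if (topology == "circular") {
    out$ct <- out$ct %% n; out$cb <- out$cb %% n
    out <- out[!duplicated(out[, c("strand", "rec_start")]), ]
  }
  out[order(out$rec_start, out$strand), ]
}

# IUPAC-aware reverse complement of a pattern (independent mapping)
oracle_revcomp_pattern <- function(p) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(toupper(p), "")[[1]]]), collapse = "")
}

# minimal rotation by trying every start (quadratic, fine at oracle scale)
oracle_min_rotation <- function(s) {
  n <- nchar(s)
  d <- paste0(s, s)
  min(vapply(0:(n - 1L), function(i) substr(d, i + 1L, i + n), character(1)))
}

oracle_circ_canonical <- function(s) {
  min(oracle_min_rotation(s), oracle_min_rotation(oracle_revcomp(s)))
}

# Brute-force enumeration of circular ligation products from fragments
# described as list(bases=, l=, r=) where l/r are the 5' overhang strings as
# written on the protruding strand (l = left end, r = right end; "" = blunt).
# Every subset x ordering x orientation assignment is tested; the leader of
# each subset is pinned to position 1 in + orientation (a circle and its
# flip are the same molecule).
oracle_assemble <- function(frags, max_cycle = 6L) {
  m <- length(frags)
  flip <- function(f) list(bases = oracle_revcomp(f$bases), l = f$r, r = f$l)
  compat <- function(a, b) nchar(a$r) == nchar(b$l) &&
    a$r == oracle_revcomp(b$l)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  found <- character()
  subsets <- unlist(lapply(seq_len(min(m, max_cycle)), function(k)
    utils::combn(m, k, simplify = FALSE)), recursive = FALSE)
  for (sub in subsets) {
    leader <- sub[1]
    rest <- sub[-1]
    for (ord in perms(rest)) {
      k <- length(ord)
      for (mask in 0:(2^k - 1)) {
        chain <- list(frags[[leader]])
        if (k) for (j in seq_len(k)) {
          f <- frags[[ord[j]]]
          if (bitwAnd(mask, bitwShiftL(1L, j - 1L))) f <- flip(f)
          chain[[length(chain) + 1L]] <- f
        }
        ok <- TRUE
        for (j in seq_along(chain)) {
          nxt <- chain[[if (j < length(chain)) j + 1L else 1L]]
          if (!compat(chain[[j]], nxt)) { ok <- FALSE; break }
        }
        if (!ok) next
        bases <- ""
        for (j in seq_along(chain)) {
          f <- chain[[j]]
          keep <- substr(f$bases, 1L, nchar(f$bases) - nchar(f$r))
          bases <- paste0(bases, keep)
        }
        found <- c(found, oracle_circ_canonical(bases))
      }
    }
  }
  sort(unique(found))
}

# plain string surgery: replace genome[ue, ds) with insert
oracle_surgery <- function(genome, up, down, insert) {
  us <- regexpr(up, genome, fixed = TRUE)[1] - 1L
  ds_ <- regexpr(down, genome, fixed = TRUE)[1] - 1L
  ue <- us + nchar(up)
  paste0(substr(genome, 1L, ue), insert,
         substr(genome, ds_ + 1L, nchar(genome)))
}

rand_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# remove all assembly-enzyme + ApaI recognition occurrences from a test
# sequence (simple midpoint substitution, independent of the package)
scrub_all <- function(s) {
  pats <- c("GGTCTC", "GAGACC", "GAAGAC", "GTCTTC", "CGTCTC", "GAGACG",
            "GCGATG", "CATCGC", "CACCTGC", "GCAGGTG", "GGGCCC")
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  repeat {
    dirty <- FALSE
    for (p in pats) {
      i <- regexpr(p, s, fixed = TRUE)[1]
      while (i > 0) {
        mid <- i + nchar(p) %/% 2L
        substr(s, mid, mid) <- swap[[substr(s, mid, mid)]]
        dirty <- TRUE
        i <- regexpr(p, s, fixed = TRUE)[1]
      }
    }
    if (!dirty) return(s)
  }
}
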