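#' Design of assembly-ready parts for a target locus
#'
#' Turns a genome plus target locus into everything a one-pot assembly
#' needs: homology arms, an enzyme choice free of internal sites, primers
#' with type IIS tails that expose the correct junction overhangs after
#' digestion, multi-enzyme polylinkers, and SEVA compliance checks.
#'
#' @name design
NULL

# fixed spacer/pad pool; variants rotate the read-out position so that an
# accidentally created recognition site can be padded away deterministically
.spacer_pool <- "ATCAGTACTGATACTAGTCAGATCTGATCAGCTATCAGATACGATCAGTA"

spacer_chars <- function(len, variant = 0L) {
  if (len <= 0) return("")
  pool <- .spacer_pool
  idx <- ((variant * 7L + seq_len(len) - 1L) %% nchar(pool)) + 1L
  paste(substring(pool, idx, idx), collapse = "")
}

#' Extract homology arms around a deletion interval
#'
#' The `up` arm is the `arm_length` bases immediately 5' of the interval on
#' the forward strand, `down` the bases immediately 3'.  A zero-length
#' interval (insertion without deletion) is allowed.  Arms shorter than
#' 400 bp draw a warning (integration efficiency drops markedly); below the
#' hard floor of 70 bp the design is rejected.
#'
#' @param genome a [ds_seq()] (linear or circular).
#' @param interval integer pair `c(start, end)`, 0-based half-open deletion
#'   interval on the forward strand; or `NULL` if `feature` is given.
#' @param feature feature label on `genome` to delete (resolved via its
#'   annotations).
#' @param arm_length length of each arm in bp; a single value or
#'   `c(up, down)`.  Default 400.
#' @return list with `up` and `down` (linear [ds_seq()]), plus the resolved
#'   `interval`.
#' @export
extract_arms <- function(genome, interval = NULL, feature = NULL,
                         arm_length = 400L) {
  if (!inherits(genome, "ds_seq")) stop("`genome` must be a ds_seq")
  if (is.null(interval)) {
    if (is.null(feature)) stop("give either `interval` or `feature`")
    f <- genome$features
    i <- which(f$label == feature)
    if (length(i) != 1L) stop(sprintf("feature '%s' not found exactly once", feature))
    interval <- c(f$start[i], f$end[i])
  }
  arm_length <- as.integer(rep(arm_length, length.out = 2L))
  if (any(arm_length < 70L))
    stop("arm length below the 70 bp hard floor is rejected")
  if (any(arm_length < 400L))
    warning("arm length < 400 bp is not recommended due to the significantly reduced integration efficiency")
  n <- ds_length(genome)
  s <- interval[1]; e <- interval[2]
  if (s < 0 || e > n || s > e) stop("interval off-genome")
  if (genome$topology == "linear" &&
      (s - arm_length[1] < 0 || e + arm_length[2] > n))
    stop("arm region extends beyond the linear genome")
  if (arm_length[1] + arm_length[2] + (e - s) > n)
    stop("arm regions overlap each other")
  up <- ds_seq(ds_slice(genome, s - arm_length[1], s), "linear",
               id = "up_arm")
  up <- add_feature(up, "up", 0L, arm_length[1])
  down <- ds_seq(ds_slice(genome, e, e + arm_length[2]), "linear",
                 id = "down_arm")
  down <- add_feature(down, "down", 0L, arm_length[2])
  list(up = up, down = down, interval = c(s, e))
}

#' Choose an assembly enzyme with no internal sites
#'
#' Returns the first candidate with zero cleavable recognition sites in
#' every supplied sequence.  The default priority BsaI > BbsI > BsmBI >
#' AarI reflects validated assembly efficiency (the first three >95%; AarI
#' has lower activity but a rarer 7 bp site); BtgZI is never auto-selected
#' because one-pot assembly with it could not be validated.
#'
#' @param sequences list of [ds_seq()] (arms and chosen entry vectors).
#' @param candidates ordered character vector of enzyme names.
#' @return an [enzyme()]; attribute `"report"` holds per-enzyme site counts.
#' @export
select_enzyme <- function(sequences,
                          candidates = c("BsaI", "BbsI", "BsmBI", "AarI")) {
  if (inherits(sequences, "ds_seq")) sequences <- list(sequences)
  counts <- vapply(candidates, function(nm) {
    sum(vapply(sequences, function(s) {
      h <- find_sites(s, nm); sum(h$cleavable)
    }, numeric(1)))
  }, numeric(1))
  report <- data.frame(enzyme = candidates, sites = as.integer(counts),
                       stringsAsFactors = FALSE)
  ok <- which(counts == 0L)
  if (!length(ok))
    stop("all candidate enzymes have sites in the supplied sequences; ",
         "remove the sites or use the storage-vector route (blunt cloning ",
         "into the EcoRV-linearized up/down storage vectors)")
  e <- enzyme(candidates[ok[1]])
  attr(e, "report") <- report
  e
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH kcal/mol, dS cal/(mol K); duplex read 5'->3' on the top strand.
.nn_dh <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
.nn_ds <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Unified nearest-neighbor model with the standard initiation terms and a
#' sodium entropy correction (0.368 * N * ln\[Na+\]).  Defaults: 0.5 uM
#' primer, 50 mM monovalent salt.  Deterministic, so designed primers are
#' reproducible bit for bit.
#'
#' @param seq primer sequence (ACGT).
#' @param primer_conc total strand concentration, mol/L.
#' @param na monovalent cation concentration, mol/L.
#' @return melting temperature in degrees Celsius.
#' @export
nn_tm <- function(seq, primer_conc = 5e-7, na = 0.05) {
  s <- toupper(seq)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(ch) < 2) stop("sequence too short for the nearest-neighbor model")
  dh <- 0; ds <- 0
  for (i in seq_len(length(ch) - 1L)) {
    pair <- paste0(ch[i], ch[i + 1L])
    if (pair %in% names(.nn_dh)) {
      dh <- dh + .nn_dh[[pair]]; ds <- ds + .nn_ds[[pair]]
    } else {
      rc <- dna_revcomp(pair) # complementary stack has identical energetics
      dh <- dh + .nn_dh[[rc]]; ds <- ds + .nn_ds[[rc]]
    }
  }
  for (term in ch[c(1L, length(ch))]) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds + (-2.8) }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds_salt <- ds + 0.368 * (length(ch) - 1L) * log(na)
  r <- 1.987
  dh * 1000 / (ds_salt + r * log(primer_conc / 4)) - 273.15
}

#' Simulate PCR on a template
#'
#' Locates the exact annealing regions (the 3'-terminal `anneal` bases of
#' each primer; the reverse primer anneals to the forward strand as its
#' reverse complement), requires both to be unique, and emits the
#' blunt-ended product including both primer tails.
#'
#' @param template a [ds_seq()].
#' @param fwd,rev full primer sequences 5'->3'.
#' @param anneal_fwd,anneal_rev annealing lengths (3'-terminal bases used
#'   for template search).
#' @return linear blunt [ds_seq()].
#' @export
simulate_pcr <- function(template, fwd, rev, anneal_fwd, anneal_rev) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  n <- ds_length(template)
  subj <- if (template$topology == "circular") paste0(template$bases, template$bases)
          else template$bases
  fa <- substr(fwd, nchar(fwd) - anneal_fwd + 1L, nchar(fwd))
  ra <- substr(rev, nchar(rev) - anneal_rev + 1L, nchar(rev))
  ra_rc <- dna_revcomp(ra)
  sf <- pattern_starts(subj, fa)
  sr <- pattern_starts(subj, ra_rc)
  if (template$topology == "circular") { sf <- unique(sf %% n); sr <- unique(sr %% n) }
  if (length(sf) != 1L) stop("forward primer anneals ", length(sf), " times; need exactly 1")
  if (length(sr) != 1L) stop("reverse primer anneals ", length(sr), " times; need exactly 1")
  if (template$topology == "circular" && sr < sf) sr <- sr + n
  if (sr + anneal_rev < sf + anneal_fwd) stop("primers face away from each other")
  core <- ds_slice(template, sf + anneal_fwd, sr + anneal_rev)
  rev_tail <- substr(rev, 1L, nchar(rev) - anneal_rev)
  out <- ds_seq(paste0(fwd, core, dna_revcomp(rev_tail)), "linear")
  out$meta$amplicon <- c(sf, sr + anneal_rev)
  out
}

primer_tail <- function(e, overhang, variant = 0L, pad_len = 4L) {
  paste0(spacer_chars(pad_len, variant + 3L), e$recognition,
         spacer_chars(e$cut_top, variant), overhang)
}

#' Design a primer pair for a homology arm
#'
#' Tails follow the layout 5' pad (4 nt), enzyme recognition site, spacer
#' (so the cut lands exactly on the fusion window), fusion-site overhang,
#' then the annealing region.  Up arms receive the B overhang on the outer
#' (forward) side and C on the inner (reverse) side; down arms E inner /
#' F outer.  The annealing region grows from 18 nt until the predicted
#' nearest-neighbor Tm reaches 60 C (or 30 nt).  Before returning, the pair
#' is verified by simulated PCR and digestion: the released fragment must
#' carry exactly the intended overhangs.  If a tail creates an unintended
#' recognition site, up to 16 alternative spacer/pad variants are tried.
#'
#' With `storage_route = TRUE` the function instead emits tail-less primers
#' for blunt cloning into the EcoRV-linearized storage vectors (the vector
#' then contributes the polylinker; orientation must be verified by
#' sequencing).
#'
#' @param arm linear [ds_seq()] (from [extract_arms()]).
#' @param side `"up"` or `"down"`.
#' @param enz assembly [enzyme()] or name.
#' @param tm_target annealing Tm target, degrees C.
#' @param anneal_min,anneal_max annealing-length bounds, nt.
#' @param storage_route emit tail-less primers for the storage-vector route.
#' @return object of class `primer_pair`.
#' @export
design_primers <- function(arm, side = c("up", "down"), enz,
                           tm_target = 60, anneal_min = 18L, anneal_max = 30L,
                           storage_route = FALSE) {
  side <- match.arg(side)
  e <- enzyme(enz)
  n <- ds_length(arm)
  grow <- function(s) { # annealing region from a sequence 5' end
    len <- anneal_min
    while (len < anneal_max && nn_tm(substr(s, 1L, len)) < tm_target)
      len <- len + 1L
    len
  }
  fa_len <- grow(arm$bases)
  rc <- dna_revcomp(arm$bases)
  ra_len <- grow(rc)
  if (n < max(fa_len, ra_len)) stop("arm shorter than the annealing length")
  fwd_anneal <- substr(arm$bases, 1L, fa_len)
  rev_anneal <- substr(rc, 1L, ra_len)

  if (storage_route) {
    sv <- if (side == "up") "pSEVA243X" else "pSEVA243Y"
    pp <- structure(list(
      fwd = fwd_anneal, rev = rev_anneal, side = side, enzyme = NA_character_,
      anneal_fwd = fa_len, anneal_rev = ra_len,
      tm_fwd = nn_tm(fwd_anneal), tm_rev = nn_tm(rev_anneal),
      storage_vector = sv, layout = list(storage_route = TRUE)
    ), class = "primer_pair")
    return(pp)
  }

  oh <- if (side == "up") c(junction_overhang("B"), junction_overhang("C"))
        else c(junction_overhang("E"), junction_overhang("F"))
  left_oh <- oh[1]; right_oh <- oh[2]

  for (v in 0:15) {
    fwd <- paste0(primer_tail(e, left_oh, v), fwd_anneal)
    rev <- paste0(primer_tail(e, dna_revcomp(right_oh), v + 1L), rev_anneal)
    prod <- simulate_pcr(arm, fwd, rev, fa_len, ra_len)
    hits <- find_sites(prod, e)
    if (nrow(hits) != 2L || !all(hits$cleavable)) next
    frs <- tryCatch(digest(prod, e), error = function(err) NULL)
    if (is.null(frs) || length(frs) != 3L) next
    mid <- frs[[2]]
    expect_bases <- paste0(left_oh, arm$bases, right_oh)
    if (mid$bases != expect_bases) next
    if (mid$left_end$overhang != left_oh ||
        mid$right_end$overhang != dna_revcomp(right_oh)) next
    return(structure(list(
      fwd = fwd, rev = rev, side = side, enzyme = e$name,
      anneal_fwd = fa_len, anneal_rev = ra_len,
      tm_fwd = nn_tm(fwd_anneal), tm_rev = nn_tm(rev_anneal),
      layout = list(pad = 4L, spacer_variant = v,
                    left_overhang = left_oh, right_overhang = right_oh)
    ), class = "primer_pair"))
  }
  stop("could not place primer tails without creating an unintended ",
       "recognition site (16 pad variants tried)")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair %s side, enzyme %s>\n", x$side, x$enzyme))
  cat(sprintf("  fwd (%2d nt anneal, Tm %.1f C): %s\n", x$anneal_fwd, x$tm_fwd, x$fwd))
  cat(sprintf("  rev (%2d nt anneal, Tm %.1f C): %s\n", x$anneal_rev, x$tm_rev, x$rev))
  invisible(x)
}

#' Synthesize a multi-enzyme polylinker (MCS-IIS)
#'
#' Emits a sequence containing one recognition site per requested type IIS
#' enzyme, each positioned so that its cut excises exactly the given 4 nt
#' overhang, and no enzyme in the set has any additional site.  Placement is
#' greedy left-to-right with minimal spacers (one unit of
#' recognition + spacer + overhang per enzyme), deterministic for fixed
#' inputs; spacer variants are rotated if a junction of two units creates a
#' spurious site.  In `"forward"` orientation the excised part lies to the
#' right of the fusion window (all recognition sites are left of their
#' windows); `"reverse"` is the mirror image for a part ending at the
#' junction.
#'
#' @param enzymes character vector or list of type IIS enzymes with 4 nt 5'
#'   overhangs.
#' @param overhang 4 nt non-palindromic fusion-site overhang.
#' @param orientation `"forward"` or `"reverse"`.
#' @param max_len length cap for the emitted sequence (default 120 nt).
#' @return linear [ds_seq()] with `*_site` and `fusion_window` features.
#' @export
design_mcs_iis <- function(enzymes, overhang, orientation = c("forward", "reverse"),
                           max_len = 120L) {
  orientation <- match.arg(orientation)
  enzymes <- lapply(enzymes, enzyme)
  overhang <- toupper(overhang)
  if (nchar(overhang) != 4L) stop("overhang must be 4 nt")
  if (overhang == dna_revcomp(overhang)) stop("overhang must be non-palindromic")
  if (orientation == "reverse") {
    # the mirror image: a part ending at the junction must end with the
    # overhang on the forward strand, so design the forward polylinker for
    # the reverse complement and flip the whole molecule
    out <- ds_revcomp(design_mcs_iis(enzymes, dna_revcomp(overhang),
                                     orientation = "forward", max_len = max_len))
    out$features$label <- sub(paste0("fusion_window_", dna_revcomp(overhang)),
                              paste0("fusion_window_", overhang),
                              out$features$label, fixed = TRUE)
    out$meta$overhang <- overhang
    out$meta$orientation <- "reverse"
    return(out)
  }
  for (e in enzymes) {
    if (e$kind != "IIS" || (e$cut_bottom - e$cut_top) != 4L)
      stop("all enzymes must be type IIS with 4 nt 5' overhangs: ", e$name)
  }
  for (v in 0:31) {
    units <- character(); feats <- empty_features(); pos <- 0L
    for (k in seq_along(enzymes)) {
      e <- enzymes[[k]]
      unit <- paste0(e$recognition, spacer_chars(e$cut_top, v + k), overhang)
      feats <- rbind(feats, data.frame(
        label = c(paste0(e$name, "_site"), paste0("fusion_window_", overhang)),
        start = c(pos, pos + nchar(e$recognition) + e$cut_top),
        end = c(pos + nchar(e$recognition), pos + nchar(unit)),
        strand = "+", stringsAsFactors = FALSE))
      units <- c(units, unit); pos <- pos + nchar(unit)
    }
    s <- paste(units, collapse = "")
    if (nchar(s) > max_len)
      stop(sprintf("unsatisfiable placement: %d nt exceeds the %d nt cap",
                   nchar(s), max_len))
    ds <- ds_seq(s, "linear", features = feats)
    ok <- TRUE
    for (k in seq_along(enzymes)) {
      e <- enzymes[[k]]
      hits <- find_sites(ds, e)
      if (nrow(hits) != 1L || hits$strand != "+" || !hits$cleavable) { ok <- FALSE; break }
      win <- substr(s, hits$cut_top_pos + 1L, hits$cut_bottom_pos)
      if (win != overhang) { ok <- FALSE; break }
    }
    if (ok) {
      ds$meta$overhang <- overhang
      ds$meta$orientation <- "forward"
      return(ds)
    }
  }
  stop("unsatisfiable placement: no spacer variant avoids spurious sites")
}

#' Check a vector against the SEVA layout rules
#'
#' Reports (i) every cleavable site of a forbidden enzyme that does not lie
#' inside a feature annotated with that enzyme's name (the sanctioned
#' boundary positions), (ii) part-order violations against the canonical
#' layout up - cargo - Bacillus marker - down - T0 - bla - oriT - ori - T1,
#' and (iii) a Bacillus marker transcribed co-directionally with the cargo
#' (it must run opposite).  The forbidden set defaults to the named SEVA
#' boundary enzymes (AscI, SwaI) plus MluI for marker exchange and is
#' configurable data, not code.
#'
#' @param vector annotated [ds_seq()].
#' @param forbidden character vector of enzyme names.
#' @return list with `pass` (logical) and `findings` (data.frame with
#'   `type`, `enzyme`, `position`, `message`), class `compliance_report`.
#' @export
check_seva_compliance <- function(vector,
                                  forbidden = c("AscI", "SwaI", "MluI")) {
  if (!inherits(vector, "ds_seq")) stop("`vector` must be a ds_seq")
  if (!nrow(vector$features))
    stop("vector carries no part annotations; annotate parts before checking")
  f <- vector$features
  findings <- data.frame(type = character(), enzyme = character(),
                         position = integer(), message = character(),
                         stringsAsFactors = FALSE)
  note <- function(type, enzyme, position, message)
    findings[nrow(findings) + 1L, ] <<- list(type, enzyme, as.integer(position), message)

  for (nm in forbidden) {
    hits <- find_sites(vector, nm)
    hits <- hits[hits$cleavable, , drop = FALSE]
    for (i in seq_len(nrow(hits))) {
      s <- hits$rec_start[i]
      sanctioned <- f[f$label == nm, , drop = FALSE]
      ok <- nrow(sanctioned) &&
        any(s >= sanctioned$start & s < sanctioned$end)
      if (!ok) note("forbidden_site", nm, s,
                    sprintf("%s site at %d outside any sanctioned boundary", nm, s))
    }
  }

  order_labels <- c("up", "cargo", "bsu_marker", "down", "T0", "bla",
                    "oriT", "ori", "T1")
  present <- f[f$label %in% order_labels, , drop = FALSE]
  present <- present[order(present$start), , drop = FALSE]
  if (nrow(present) >= 2L) {
    lab <- present$label
    expect <- order_labels[order_labels %in% lab]
    ok_order <- FALSE
    seqs <- if (vector$topology == "circular") {
      lapply(seq_along(lab) - 1L, function(r) c(lab, lab)[seq_along(lab) + r])
    } else list(lab)
    for (cand in seqs) {
      if (identical(cand, expect) || identical(rev(cand), expect)) { ok_order <- TRUE; break }
    }
    if (!ok_order)
      note("part_order", NA_character_, present$start[1],
           sprintf("part order %s does not match the canonical layout",
                   paste(lab, collapse = " - ")))
  }

  cargo_strand <- f$strand[f$label == "cargo"]
  marker_strand <- f$strand[f$label == "bsu_marker"]
  if (length(cargo_strand) == 1L && length(marker_strand) == 1L &&
      cargo_strand == marker_strand)
    note("marker_orientation", NA_character_, f$start[f$label == "bsu_marker"][1],
         "Bacillus marker is transcribed co-directionally with the cargo; it must run opposite")

  structure(list(pass = nrow(findings) == 0L, findings = findings),
            class = "compliance_report")
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf("<compliance %s: %d finding(s)>\n",
              if (x$pass) "PASS" else "FAIL", nrow(x$findings)))
  if (nrow(x$findings)) print(x$findings)
  invisible(x)
}

#' Full design report for a locus
#'
#' Convenience wrapper: extracts arms, picks the enzyme, designs primers
#' for both arms and suggests the final-vector name.
#'
#' @param genome annotated [ds_seq()].
#' @param interval,feature locus specification as in [extract_arms()].
#' @param arm_length arm length(s), bp.
#' @param cargo,destination entry-vector names for the name suggestion
#'   (registry names).
#' @param locus locus label for the suggested name.
#' @param extra_sequences additional [ds_seq()]s (e.g. actual entry-vector
#'   sequences) that must stay free of the chosen enzyme's sites.
#' @return list of class `design_report`.
#' @export
design_locus <- function(genome, interval = NULL, feature = NULL,
                         arm_length = 400L, cargo = "pBSc241M",
                         destination = "pBSd141R", locus = feature,
                         extra_sequences = list()) {
  arms <- extract_arms(genome, interval, feature, arm_length)
  enz <- select_enzyme(c(list(arms$up, arms$down), extra_sequences))
  up_pp <- design_primers(arms$up, "up", enz)
  down_pp <- design_primers(arms$down, "down", enz)
  structure(list(
    enzyme = enz$name, enzyme_report = attr(enz, "report"),
    arms = arms, primers = list(up = up_pp, down = down_pp),
    suggested_name = suggest_name(destination, cargo, locus)
  ), class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("<design_report enzyme=%s name=%s>\n", x$enzyme, x$suggested_name))
  print(x$primers$up); print(x$primers$down)
  invisible(x)
}

#' Amplify an arm into an assembly-ready entry part
#'
#' Runs the simulated PCR for a designed primer pair and annotates the
#' product so it can act directly as an `up`/`down` entry part: the arm
#' interval is labelled with the side, and id/role are set for the
#' assembly classifier.
#'
#' @param arm the template arm ([ds_seq()]).
#' @param pp a `primer_pair` from [design_primers()].
#' @return linear [ds_seq()] PCR product.
#' @export
amplify_arm <- function(arm, pp) {
  if (isTRUE(pp$layout$storage_route))
    stop("storage-route primer pairs have no tails; clone the product into ",
         "the storage vector instead")
  prod <- simulate_pcr(arm, pp$fwd, pp$rev, pp$anneal_fwd, pp$anneal_rev)
  tail_len <- nchar(pp$fwd) - pp$anneal_fwd
  prod <- add_feature(prod, pp$side, tail_len, tail_len + ds_length(arm))
  prod$id <- paste0(pp$side, "_part")
  prod$role <- pp$side
  prod
}
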