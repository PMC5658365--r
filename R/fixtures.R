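#' Deterministic synthetic fixtures
#'
#' Generates toy genomes and structurally correct entry-part sets so that
#' every operation in the package is testable without any downloads.
#' Placeholder genes (bla, neo, mRFP1, mkate2, lacZ-alpha, ...) are short
#' random sentinel sequences with feature labels, not real ORFs: the
#' screening and classification logic keys on labels, so sequence realism
#' is unnecessary at desk scale.  All generation is integer/string based
#' and fully determined by the seed.
#'
#' @name fixtures
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# destroy every occurrence of the given enzymes' recognition patterns by a
# deterministic single-base substitution in the footprint middle; iterate
# until clean (bounded).
scrub_sites <- function(bases, enzymes, max_iter = 30L) {
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  for (it in seq_len(max_iter)) {
    dirty <- FALSE
    for (nm in enzymes) {
      e <- enzyme(nm)
      for (pat in unique(c(e$recognition, dna_revcomp(e$recognition)))) {
        starts <- pattern_starts(bases, pat)
        if (length(starts)) {
          dirty <- TRUE
          for (s in starts) {
            mid <- s + nchar(pat) %/% 2L
            cur <- substr(bases, mid + 1L, mid + 1L)
            substr(bases, mid + 1L, mid + 1L) <- swap[[cur]]
          }
        }
      }
    }
    if (!dirty) return(bases)
  }
  stop("site exclusion infeasible after bounded retries")
}

# Remove recognition-site occurrences that are not fully inside a protected
# interval by mutating one occurrence base that falls in mutable territory.
# `protected` is a 2-column matrix of 0-based half-open intervals.  The scan
# wraps the origin for circular sequences.  Enzymes in `lenient` are fixed
# best-effort: an occurrence wedged entirely between protected intervals is
# tolerated (it does not affect the assembly chemistry), whereas for the
# remaining (strict) enzymes it is an error.
fix_spurious_sites <- function(bases, topology, enzymes, protected,
                               max_iter = 30L,
                               lenient = c("AscI", "SwaI", "MluI")) {
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  n <- nchar(bases)
  inside_protected <- function(s, e) {
    if (!nrow(protected)) return(FALSE)
    any(s >= protected[, 1] & e <= protected[, 2])
  }
  pos_protected <- function(p) {
    p <- p %% n
    nrow(protected) && any(p >= protected[, 1] & p < protected[, 2])
  }
  for (it in seq_len(max_iter)) {
    subj <- if (topology == "circular") paste0(bases, substr(bases, 1L, 12L)) else bases
    dirty <- FALSE
    for (nm in enzymes) {
      e <- enzyme(nm)
      for (pat in unique(c(e$recognition, dna_revcomp(e$recognition)))) {
        lp <- nchar(pat)
        starts <- pattern_starts(subj, pat)
        if (topology == "circular") starts <- unique(starts[starts < n])
        for (s in starts) {
          if (inside_protected(s, s + lp)) next
          cand <- (s:(s + lp - 1L)) %% n
          cand <- cand[!vapply(cand, pos_protected, logical(1))]
          if (!length(cand)) {
            if (nm %in% lenient) next
            stop("cannot remove a spurious ", nm,
                 " site spanning protected intervals")
          }
          mid <- cand[ceiling(length(cand) / 2)]
          cur <- substr(bases, mid + 1L, mid + 1L)
          substr(bases, mid + 1L, mid + 1L) <- swap[[cur]]
          dirty <- TRUE
        }
      }
    }
    if (!dirty) return(bases)
  }
  stop("site exclusion infeasible after bounded retries")
}

#' Fixture configuration
#'
#' The defaults define the study conditions all tests run under: a
#' Bacillus-like GC fraction, 400 bp homology arms, BsaI as the assembly
#' enzyme, and loci that include a >= 10 kb "prophage" so that large
#' deletions are exercised routinely (the 130 kb prophage-scale case is
#' produced by overriding `loci`/`genome_length`).
#'
#' @param seed integer seed; every derived sequence is a pure function of it.
#' @param genome_length toy genome size in bp.
#' @param gc GC fraction of random sequence.
#' @param loci data.frame with columns `name` and `del_len` (deletion
#'   interval length per locus); intervals are spread evenly along the
#'   genome.
#' @param arm_length homology-arm length, bp.
#' @param enzyme assembly enzyme for the entry set.
#' @param scrub_enzymes enzymes whose sites are excluded from all random
#'   sequence: the five assembly enzymes, ApaI (so linearization stays
#'   unique) and the SEVA boundary/exchange enzymes (so generated vectors
#'   are compliant by construction).
#' @param cargo_reporter `"none"`, `"lacZalpha"` or `"mkate2"`: reporter
#'   sentinel placed in the cargo.
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, genome_length = 50000L, gc = 0.43,
                           loci = data.frame(
                             name = c("amyE", "prophage", "thrC"),
                             del_len = c(2000L, 12000L, 1000L),
                             stringsAsFactors = FALSE),
                           arm_length = 400L, enzyme = "BsaI",
                           scrub_enzymes = c(assembly_enzymes(), "ApaI",
                                             "AscI", "SwaI", "MluI"),
                           cargo_reporter = "none") {
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 gc = gc, loci = loci, arm_length = as.integer(arm_length),
                 enzyme = enzyme, scrub_enzymes = scrub_enzymes,
                 cargo_reporter = cargo_reporter),
            class = "fixture_config")
}

#' Generate a toy genome with annotated loci
#'
#' Seeded random circular genome; recognition sites of the configured
#' enzymes are excluded everywhere (none are intentionally planted), and
#' each configured locus is annotated as a feature spanning its deletion
#' interval.
#'
#' @param cfg a [fixture_config()].
#' @return circular [ds_seq()].
#' @export
make_toy_genome <- function(cfg = fixture_config()) {
  loci <- cfg$loci
  need <- sum(loci$del_len) + 2L * nrow(loci) * cfg$arm_length + 1000L
  if (cfg$genome_length < need)
    stop(sprintf("genome_length %d too small for the configured loci (need >= %d)",
                 cfg$genome_length, need))
  with_seed(cfg$seed, {
    bases <- scrub_sites(rand_dna(cfg$genome_length, cfg$gc), cfg$scrub_enzymes)
    # also clean the two ends of the circle junction
    bases <- fix_spurious_sites(bases, "circular", cfg$scrub_enzymes,
                                matrix(numeric(), 0, 2))
    g <- ds_seq(bases, "circular", id = sprintf("toy_genome_seed%d", cfg$seed))
    # spread locus intervals evenly, away from the origin
    n <- nrow(loci)
    anchors <- floor(cfg$genome_length * (seq_len(n)) / (n + 1L))
    for (i in seq_len(n)) {
      s <- anchors[i]
      g <- add_feature(g, loci$name[i], s, s + loci$del_len[i])
    }
    g
  })
}

#' Generate a structurally correct entry-part set
#'
#' Builds toy versions of the four entry parts: an `up` and a `down`
#' homology fragment flanked by full five-enzyme polylinkers
#' ([design_mcs_iis()]), a cargo-resistance vector (cargo sentinel plus a
#' Bacillus marker transcribed in the opposite direction, between the C and
#' E junction polylinkers), and a destination vector (mRFP1 stuffer between
#' the B and F polylinkers; backbone T0 - bla - oriT - ori - T1 with a
#' unique ApaI site inside the ori).  Spurious recognition sites spanning
#' block boundaries are removed deterministically without touching the
#' polylinkers, the planted ApaI site, or user-supplied arms.  The set
#' self-checks at generation time: a one-pot assembly must yield exactly
#' one final vector.
#'
#' @param cfg a [fixture_config()].
#' @param arms optional list with `up`/`down` [ds_seq()] (e.g. real arms
#'   from [extract_arms()]); random arms of `cfg$arm_length` are generated
#'   otherwise.
#' @param self_check run the generation-time assembly check (default TRUE).
#' @return named list of [ds_seq()]: `up`, `down`, `cargo_resistance`,
#'   `destination`.
#' @export
make_entry_set <- function(cfg = fixture_config(), arms = NULL,
                           self_check = TRUE) {
  scrub <- cfg$scrub_enzymes
  gc <- cfg$gc
  mcs_fwd <- function(j) design_mcs_iis(assembly_enzymes(), junction_overhang(j))
  mcs_rev <- function(j) design_mcs_iis(assembly_enzymes(), junction_overhang(j),
                                    orientation = "reverse")
  arms_supplied <- !is.null(arms)

  with_seed(cfg$seed + 1000L, {
    if (is.null(arms)) {
      up_arm <- ds_seq(scrub_sites(rand_dna(cfg$arm_length, gc), scrub),
                       id = "up_arm")
      up_arm <- add_feature(up_arm, "up", 0L, cfg$arm_length)
      down_arm <- ds_seq(scrub_sites(rand_dna(cfg$arm_length, gc), scrub),
                         id = "down_arm")
      down_arm <- add_feature(down_arm, "down", 0L, cfg$arm_length)
      arms <- list(up = up_arm, down = down_arm)
    }

    sentinel <- function(label, len, strand = "+") {
      list(label = label, bases = scrub_sites(rand_dna(len, gc), scrub),
           strand = strand, protected = FALSE)
    }
    # blocks: ds_seq (polylinkers, protected), sentinel lists, or arm
    # markers (protected iff supplied by the caller)
    build <- function(blocks, topology, id, role) {
      bases <- ""; feats <- empty_features()
      prot <- matrix(numeric(), 0, 2)
      for (b in blocks) {
        at <- nchar(bases)
        if (inherits(b, "ds_seq")) {
          f <- b$features
          if (nrow(f)) { f$start <- f$start + at; f$end <- f$end + at }
          feats <- rbind(feats, f)
          bases <- paste0(bases, b$bases)
          is_arm <- !is.null(b$id) && b$id %in% c("up_arm", "down_arm")
          if (!is_arm || arms_supplied)
            prot <- rbind(prot, c(at, at + ds_length(b)))
        } else {
          feats <- rbind(feats, data.frame(
            label = b$label, start = at, end = at + nchar(b$bases),
            strand = b$strand, stringsAsFactors = FALSE))
          if (!is.null(b$protected_range))
            prot <- rbind(prot, at + b$protected_range)
          else if (isTRUE(b$protected))
            prot <- rbind(prot, c(at, at + nchar(b$bases)))
          bases <- paste0(bases, b$bases)
        }
      }
      bases <- fix_spurious_sites(bases, topology, scrub, prot)
      ds_seq(bases, topology, features = feats, id = id, role = role)
    }

    up <- build(list(mcs_fwd("B"), arms$up, mcs_rev("C")), "linear", "up_part", "up")
    down <- build(list(mcs_fwd("E"), arms$down, mcs_rev("F")), "linear",
                  "down_part", "down")

    cargo_blocks <- list(
      mcs_fwd("C"),
      sentinel("cargo", 150L),
      if (cfg$cargo_reporter == "lacZalpha") sentinel("lacZalpha", 90L)
      else if (cfg$cargo_reporter == "mkate2") sentinel("mkate2", 90L)
      else NULL,
      sentinel("bsu_marker", 90L, strand = "-"),
      mcs_rev("E"),
      sentinel("neo", 120L),
      sentinel("ori", 80L))
    cargo_blocks <- Filter(Negate(is.null), cargo_blocks)
    cargo <- build(cargo_blocks, "circular", "cargo_part", "cargo_resistance")

    # ori sentinel with the planted, protected ApaI linearization site
    ori_hi <- sentinel("ori", 90L)
    at <- (nchar(ori_hi$bases) - 6L) %/% 2L
    substr(ori_hi$bases, at + 1L, at + 6L) <- "GGGCCC"
    ori_hi$protected_range <- c(at, at + 6L)
    dest <- build(list(
      mcs_fwd("F"),
      sentinel("T0", 30L),
      sentinel("bla", 120L),
      sentinel("oriT", 60L),
      ori_hi,
      sentinel("T1", 30L),
      mcs_rev("B"),
      sentinel("mRFP1", 90L)), "circular", "dest_part", "destination")
    # the planted ApaI site must be unique
    if (nrow(find_sites(dest, "ApaI")) != 1L)
      stop("fixture self-check failed: ApaI site in the destination is not unique")

    parts <- list(up = up, down = down, cargo_resistance = cargo,
                  destination = dest)
    if (self_check) {
      prods <- golden_gate(parts, cfg$enzyme)
      cls <- vapply(prods, `[[`, character(1), "classification")
      if (sum(cls == "final_vector") != 1L)
        stop("fixture self-check failed: entry set does not assemble to ",
             "exactly one final vector")
    }
    parts
  })
}
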