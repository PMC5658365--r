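#' Linearization and double-crossover integration
#'
#' Before transformation the final vector must be linearized in its
#' replication part so that only double homologous recombination (allelic
#' replacement) can establish the marker; a circular molecule would also
#' allow single-crossover (Campbell-type) integration, which this simulator
#' deliberately does not model.  Homology matching is exact: the mechanism
#' requires identical sequence, and sequence-divergent strains simply need
#' new arms.
#'
#' @name integrate
NULL

# is position p inside the cyclic interval [a, b) on a circle of size n?
in_cyclic <- function(p, a, b, n) {
  span <- ((b - a) %% n + n) %% n
  off <- ((p - a) %% n + n) %% n
  off < span
}

#' Linearize a circular vector at a unique site
#'
#' Cuts at the unique site of `enz` (default ApaI) and errors if the cut
#' would fall inside the integration part (between the outer boundaries of
#' the up and down arms): linearization must happen in the replication
#' part.  The returned linear molecule starts at the cut.
#'
#' @param vector circular [ds_seq()] annotated with `up` and `down`
#'   features.
#' @param enz enzyme name or [enzyme()]; default `"ApaI"`.
#' @return linear [ds_seq()] fragment.
#' @export
linearize <- function(vector, enz = "ApaI") {
  if (!inherits(vector, "ds_seq")) stop("`vector` must be a ds_seq")
  if (vector$topology != "circular") stop("`vector` must be circular")
  e <- enzyme(enz)
  f <- vector$features
  if (!all(c("up", "down") %in% f$label))
    stop("vector must carry `up` and `down` arm annotations")
  hits <- find_sites(vector, e)
  if (nrow(hits) == 0L) {
    alt <- Filter(function(nm) {
      h <- find_sites(vector, nm); nrow(h) == 1L
    }, setdiff(list_enzymes()$name, e$name))
    stop(sprintf("no %s site in the vector; unique cutters found by scanning: %s",
                 e$name,
                 if (length(alt)) paste(unlist(alt), collapse = ", ") else "none"))
  }
  if (nrow(hits) > 1L)
    stop(sprintf("%s cuts %d times; linearization needs a unique site",
                 e$name, nrow(hits)))
  n <- ds_length(vector)
  up_start <- f$start[f$label == "up"][1]
  down_end <- f$end[f$label == "down"][1]
  w <- site_cut_window(hits[1, ], e, n, TRUE)
  cutpos <- ((w$start %% n) + n) %% n
  if (in_cyclic(cutpos, up_start, down_end, n))
    stop("cut within integration part: linearize in the replication part instead")
  frs <- digest(vector, e)
  frs[[1]]
}

#' Integration result
#'
#' @param x object returned by [double_crossover()]: `genome` (edited
#'   [ds_seq()]), `deleted_interval` (0-based half-open, coordinates of the
#'   pre-edit genome as returned, possibly rotated for circular genomes),
#'   `deleted_length`, `inserted_length`, `insert` (the integrated
#'   [ds_seq()] region), `junctions` (coordinates of the two arm/insert
#'   joints in the edited genome).
#' @name integration_result
NULL

#' Simulate double-crossover integration of a linearized vector
#'
#' Locates exact, unique matches of the vector's up and down arms on the
#' same genome strand (up preceding down) and replaces the genomic interval
#' between the arm matches with the vector's integration part (everything
#' between the arms: cargo plus Bacillus marker).  Deletion lengths from 0
#' (adjacent arms) to arbitrarily large intervals are supported.  Matching
#' is exact; partial or mismatched arm hits are rejected, not repaired.
#'
#' @param genome [ds_seq()] (linear or circular).
#' @param vector linear [ds_seq()] carrying `up` and `down` arm features
#'   (see [linearize()]); passing a circular vector is an error.
#' @return object of class `integration_result`.
#' @export
double_crossover <- function(genome, vector) {
  if (!inherits(genome, "ds_seq") || !inherits(vector, "ds_seq"))
    stop("`genome` and `vector` must be ds_seq objects")
  if (vector$topology != "linear")
    stop("vector must be linearized before integration (a circular molecule ",
         "would integrate by single crossover, which is not simulated)")
  vf <- vector$features
  if (!all(c("up", "down") %in% vf$label))
    stop("vector must carry `up` and `down` arm annotations")
  u <- vf[vf$label == "up", ][1, ]; d <- vf[vf$label == "down", ][1, ]
  if (min(u$end - u$start, d$end - d$start) < 70L)
    stop("arms below the 70 bp hard floor")
  if (u$end > d$start)
    stop("up arm must precede the down arm on the linearized vector")
  up_seq <- substr(vector$bases, u$start + 1L, u$end)
  down_seq <- substr(vector$bases, d$start + 1L, d$end)
  insert_bases <- substr(vector$bases, u$end + 1L, d$start)

  locate <- function(arm) {
    subj <- Biostrings::DNAString(
      if (genome$topology == "circular") paste0(genome$bases, genome$bases)
      else genome$bases)
    n <- ds_length(genome)
    fwd <- Biostrings::start(Biostrings::matchPattern(arm, subj)) - 1L
    rev <- Biostrings::start(Biostrings::matchPattern(dna_revcomp(arm), subj)) - 1L
    if (genome$topology == "circular") {
      fwd <- sort(unique(fwd[fwd < n]))
      rev <- sort(unique(rev[rev < n]))
    }
    list(fwd = fwd, rev = rev)
  }
  lu <- locate(up_seq); ld <- locate(down_seq)
  n_up <- length(lu$fwd) + length(lu$rev)
  n_dn <- length(ld$fwd) + length(ld$rev)
  if (n_up == 0L) stop("up arm not found in the genome")
  if (n_dn == 0L) stop("down arm not found in the genome")
  if (n_up > 1L) stop("up arm matches ", n_up, " genome locations; need exactly 1")
  if (n_dn > 1L) stop("down arm matches ", n_dn, " genome locations; need exactly 1")
  up_fwd <- length(lu$fwd) == 1L
  dn_fwd <- length(ld$fwd) == 1L
  if (up_fwd != dn_fwd)
    stop("arms found on opposite genome strands")
  if (!up_fwd) {
    res <- double_crossover(ds_revcomp(genome), vector)
    res$genome <- ds_revcomp(res$genome)
    res$strand <- "-"
    return(res)
  }

  n <- ds_length(genome)
  us <- lu$fwd; ds_ <- ld$fwd
  ulen <- nchar(up_seq); dlen <- nchar(down_seq)
  work <- genome; rot <- 0L
  if (genome$topology == "circular") {
    # rotate so the up match starts at 0; coordinates below are then linear
    rot <- us
    work <- ds_rotate(genome, rot)
    us <- 0L
    ds_ <- ((ds_ - rot) %% n + n) %% n
  }
  ue <- us + ulen
  if (ds_ < ue) {
    if (genome$topology == "linear" && ds_ + dlen <= us)
      stop("arm matches are in the wrong order on the genome")
    stop("arm matches overlap")
  }
  between <- substr(work$bases, ue + 1L, ds_)
  if (identical(between, insert_bases))
    stop("arm context altered: the arms already flank this integration part ",
         "(single-copy integration; re-integration is rejected)")

  deleted_len <- ds_ - ue
  edited_bases <- paste0(substr(work$bases, 1L, ue), insert_bases,
                         substr(work$bases, ds_ + 1L, n))
  shift <- nchar(insert_bases) - deleted_len
  gf <- work$features
  if (nrow(gf)) {
    keep <- gf$end <= ue | gf$start >= ds_
    gf <- gf[keep, , drop = FALSE]
    after <- gf$start >= ds_
    gf$start[after] <- gf$start[after] + shift
    gf$end[after] <- gf$end[after] + shift
  }
  # carry over annotations of the integrated part
  inf <- vf[vf$start >= u$end & vf$end <= d$start, , drop = FALSE]
  if (nrow(inf)) {
    inf$start <- inf$start - u$end + ue
    inf$end <- inf$end - u$end + ue
  }
  feats <- rbind(gf, inf,
                 data.frame(label = c("up", "down"),
                            start = c(us, ue + nchar(insert_bases)),
                            end = c(ue, ue + nchar(insert_bases) + dlen),
                            strand = "+", stringsAsFactors = FALSE))
  feats <- feats[!duplicated(feats[, c("label", "start", "end")]), , drop = FALSE]
  feats <- feats[order(feats$start), , drop = FALSE]
  rownames(feats) <- NULL
  edited <- ds_seq(edited_bases, genome$topology, features = feats,
                   id = genome$id)
  stopifnot(ds_length(edited) == n - deleted_len + nchar(insert_bases))
  structure(list(
    genome = edited,
    deleted_interval = c(ue, ds_),
    deleted_length = deleted_len,
    inserted_length = nchar(insert_bases),
    insert = insert_bases,
    junctions = c(ue, ue + nchar(insert_bases)),
    rotation = rot, strand = "+"
  ), class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("<integration: deleted %d bp at [%d, %d), inserted %d bp>\n",
              x$deleted_length, x$deleted_interval[1], x$deleted_interval[2],
              x$inserted_length))
  print(x$genome)
  invisible(x)
}
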