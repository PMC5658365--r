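#' Toolbox registry and SEVA-sibling nomenclature
#'
#' Ships the toolbox catalog (vectors, Bacillus markers, fusion sites) as
#' human-editable TSV package data, plus the number-based nomenclature codec.
#' The fusion-site overhang for junction C (GCGA) is canonical; the B, E and
#' F overhangs are synthetic placeholders that satisfy every fusion-site
#' invariant (non-palindromic, pairwise Hamming distance >= 2, no
#' cross-reverse-complement collision) and are flagged `canonical = FALSE`
#' in the data file.
#'
#' @name registry
NULL

registry_file <- function(fname) {
  path <- system.file("extdata", fname, package = "sevaforge")
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                    na.strings = character())
}

load_registry <- function() {
  if (!is.null(.sevaforge_env$registry)) return(.sevaforge_env$registry)
  reg <- list(parts = registry_file("parts.tsv"),
              markers = registry_file("markers.tsv"),
              fusion = registry_file("fusion_sites.tsv"))
  reg$fusion$canonical <- as.logical(reg$fusion$canonical)
  # cache first: the self-check itself consults the registry via the codec
  .sevaforge_env$registry <- reg
  chk <- tryCatch(registry_selfcheck(reg), error = function(e) {
    .sevaforge_env$registry <- NULL
    stop("registry self-check errored: ", conditionMessage(e))
  })
  if (!all(chk$ok)) {
    .sevaforge_env$registry <- NULL
    stop("registry self-check failed: ",
         paste(chk$check[!chk$ok], collapse = "; "))
  }
  reg
}

# E. coli code tables (three-digit nomenclature)
ecoli_marker_codes <- function() {
  data.frame(digit = c(1L, 2L, 3L), marker = c("amp", "kan", "cm"),
             gene = c("bla", "neo", "cat"), stringsAsFactors = FALSE)
}
ori_codes <- function() {
  data.frame(digit = c(4L, 9L), ori = c("pRO1600/ColE1", "pBR322/ROP"),
             copy_number = c("high", "medium"), stringsAsFactors = FALSE)
}
cargo_codes <- function() {
  data.frame(digit = c(1L, 3L),
             cargo = c("default MCS", "lacZalpha-pUC18 MCS"),
             stringsAsFactors = FALSE)
}
descriptor_codes <- function() {
  data.frame(letter = c("R", "X", "Y"),
             meaning = c("mRFP1 stuffer (destination)",
                         "up-fragment storage", "down-fragment storage"),
             stringsAsFactors = FALSE)
}

#' List the Bacillus resistance markers
#' @return data.frame with columns `letter`, `gene`, `description`,
#'   `antibiotic`, `concentration_ug_ml`.
#' @export
list_markers <- function() load_registry()$markers

#' Fusion sites (junction overhangs) of the assembly standard
#' @return data.frame with columns `junction` (B/C/E/F), `overhang` (4 nt),
#'   `mcs_ids` (the two polylinkers realizing the junction) and `canonical`.
#' @export
fusion_sites <- function() load_registry()$fusion

#' Look up a toolbox vector by name or BGSC accession
#' @param id vector name (e.g. `"pBSc241B"`) or BGSC id (e.g. `"ECE706"`).
#' @return one-row list (class `part_record`).
#' @export
lookup_part <- function(id) {
  parts <- load_registry()$parts
  i <- match(id, parts$name)
  if (is.na(i)) i <- match(id, parts$bgsc_id)
  if (is.na(i)) stop(sprintf("unknown part name or BGSC id: '%s'", id))
  rec <- as.list(parts[i, ])
  if (nzchar(rec$bsu_marker_letter)) {
    m <- load_registry()$markers
    rec$bsu_marker <- as.list(m[match(rec$bsu_marker_letter, m$letter), ])
  }
  structure(rec, class = "part_record")
}

#' @export
print.part_record <- function(x, ...) {
  cat(sprintf("<part %s (%s) role=%s digits=%d%d%d%s>\n", x$name,
              if (nzchar(x$bgsc_id)) x$bgsc_id else "-", x$role,
              x$ecoli_marker_digit, x$ori_digit, x$cargo_digit,
              if (nzchar(x$bsu_marker_letter)) x$bsu_marker_letter else ""))
  cat(" ", x$description, "\n")
  invisible(x)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Validate the registry against its invariants
#'
#' Checks digit code sets, the kanamycin-marker/medium-copy rule, marker
#' letter uniqueness and count, fusion-site geometry (length 4,
#' non-palindromic, pairwise Hamming distance >= 2, C = GCGA), the stated
#' totals (seven Bacillus markers, two E. coli oris, eight MCS-IIS ids) and
#' that every vector name round-trips through the nomenclature codec.  The
#' stricter comparison of each overhang against the reverse complements of
#' the others is computed and reported but not enforced.
#'
#' @param reg registry list; defaults to the shipped registry.
#' @return data.frame with columns `check` and `ok`.
#' @export
registry_selfcheck <- function(reg = NULL) {
  if (is.null(reg)) reg <- load_registry()
  p <- reg$parts; m <- reg$markers; fs <- reg$fusion
  checks <- list()
  add <- function(name, ok) checks[[length(checks) + 1L]] <<- data.frame(
    check = name, ok = isTRUE(ok), stringsAsFactors = FALSE)

  add("ori digits in {4, 9}", all(p$ori_digit %in% c(4L, 9L)))
  add("E. coli marker digits in {1, 2, 3}", all(p$ecoli_marker_digit %in% 1:3))
  add("cargo digits in {1, 3}", all(p$cargo_digit %in% c(1L, 3L)))
  add("K marker only on medium-copy ori (9)",
      all(p$ori_digit[p$bsu_marker_letter == "K"] == 9L))
  add("marker letters unique", !anyDuplicated(m$letter))
  add("exactly seven Bacillus marker letters",
      nrow(m) == 7L && setequal(m$letter, c("B", "C", "K", "M", "S", "T", "Z")))
  add("exactly two E. coli oris", length(unique(p$ori_digit)) == 2L)
  add("fusion overhangs are 4 nt", all(nchar(fs$overhang) == 4L))
  add("fusion overhangs non-palindromic",
      all(fs$overhang != dna_revcomp(fs$overhang)))
  pairs_ok <- TRUE
  if (nrow(fs) > 1) for (i in 1:(nrow(fs) - 1)) for (j in (i + 1):nrow(fs))
    if (hamming(fs$overhang[i], fs$overhang[j]) < 2) pairs_ok <- FALSE
  add("pairwise Hamming distance >= 2", pairs_ok)
  add("junction C overhang is GCGA", fs$overhang[fs$junction == "C"] == "GCGA")
  add("eight MCS-IIS ids",
      length(unlist(strsplit(fs$mcs_ids, "/"))) == 8L)
  rt <- vapply(p$name, function(nm)
    identical(encode_name(decode_name(nm)), nm), logical(1))
  add("all vector names round-trip the codec", all(rt))

  out <- do.call(rbind, checks)
  # reported, not enforced: overhang vs reverse complements of the others
  rc_clash <- any(outer(fs$overhang, dna_revcomp(fs$overhang), `==`) &
                    !diag(nrow(fs)))
  attr(out, "revcomp_cross_collisions") <- rc_clash
  out
}

#' Decode a SEVA-sibling vector name
#'
#' Parses `prefix + three digits [+ letter] [+ "-" suffix]` into its coded
#' fields with human-readable expansions: first digit = E. coli resistance
#' marker, second = origin of replication, third = cargo; an optional
#' Bacillus marker letter and an integration-locus suffix follow for final
#' vectors, and R/X/Y descriptor letters mark the destination and storage
#' entry vectors.
#'
#' @param name e.g. `"pSEVA243"`, `"pBS143K-amyE"`, `"pBSd141R"`.
#' @return object of class `seva_name`.
#' @export
decode_name <- function(name) {
  m <- regmatches(name, regexec(
    "^(pSEVA|pBSc|pBSd|pBSf|pBS)([0-9])([0-9])([0-9])([A-Z]?)(?:-(.+))?$", name))[[1]]
  if (!length(m)) stop(sprintf("'%s' does not match the vector name grammar", name))
  prefix <- m[2]
  d1 <- as.integer(m[3]); d2 <- as.integer(m[4]); d3 <- as.integer(m[5])
  letter <- m[6]; suffix <- m[7]
  mk <- ecoli_marker_codes(); or <- ori_codes(); cg <- cargo_codes()
  if (!d1 %in% mk$digit) stop(sprintf("unregistered E. coli marker digit: %d", d1))
  if (!d2 %in% or$digit) stop(sprintf("unregistered ori digit: %d", d2))
  if (!d3 %in% cg$digit) stop(sprintf("unregistered cargo digit: %d", d3))
  bsu <- NULL; descriptor <- NULL
  if (nzchar(letter)) {
    ml <- list_markers()$letter
    if (letter %in% ml) bsu <- letter
    else if (letter %in% descriptor_codes()$letter) descriptor <- letter
    else stop(sprintf("unregistered letter code: '%s'", letter))
  }
  structure(list(
    name = name, prefix = prefix,
    marker_digit = d1, marker = mk$marker[mk$digit == d1],
    marker_gene = mk$gene[mk$digit == d1],
    ori_digit = d2, ori = or$ori[or$digit == d2],
    copy_number = or$copy_number[or$digit == d2],
    cargo_digit = d3, cargo = cg$cargo[cg$digit == d3],
    bsu_marker_letter = bsu, descriptor = descriptor,
    locus = if (nzchar(suffix)) suffix else NULL
  ), class = "seva_name")
}

#' @export
print.seva_name <- function(x, ...) {
  cat(sprintf("<%s: %s[%d] | %s (%s copy)[%d] | %s[%d]%s%s>\n", x$name,
              x$marker, x$marker_digit, x$ori, x$copy_number, x$ori_digit,
              x$cargo, x$cargo_digit,
              if (!is.null(x$bsu_marker_letter))
                paste0(" | Bacillus marker ", x$bsu_marker_letter) else "",
              if (!is.null(x$locus)) paste0(" | locus ", x$locus) else ""))
  invisible(x)
}

#' Encode a parsed vector name back to its string form
#' @param parsed a `seva_name` (from [decode_name()]) or a list with fields
#'   `prefix`, `marker_digit`, `ori_digit`, `cargo_digit` and optionally
#'   `bsu_marker_letter`, `descriptor`, `locus`.
#' @return character scalar; `decode_name(encode_name(x))` is the identity
#'   on all registry names.
#' @export
encode_name <- function(parsed) {
  stopifnot(!is.null(parsed$prefix))
  d1 <- parsed$marker_digit; d2 <- parsed$ori_digit; d3 <- parsed$cargo_digit
  if (!d1 %in% ecoli_marker_codes()$digit) stop("unregistered marker digit: ", d1)
  if (!d2 %in% ori_codes()$digit) stop("unregistered ori digit: ", d2)
  if (!d3 %in% cargo_codes()$digit) stop("unregistered cargo digit: ", d3)
  letter <- ""
  if (!is.null(parsed$bsu_marker_letter)) {
    if (!parsed$bsu_marker_letter %in% list_markers()$letter)
      stop("unregistered Bacillus marker letter: ", parsed$bsu_marker_letter)
    letter <- parsed$bsu_marker_letter
  } else if (!is.null(parsed$descriptor)) {
    if (!parsed$descriptor %in% descriptor_codes()$letter)
      stop("unregistered descriptor letter: ", parsed$descriptor)
    letter <- parsed$descriptor
  }
  paste0(parsed$prefix, d1, d2, d3, letter,
         if (!is.null(parsed$locus)) paste0("-", parsed$locus) else "")
}

#' Suggest a final-vector name from design choices
#' @param destination,cargo names of the destination and cargo entry vectors.
#' @param locus integration-locus label.
#' @return suggested `pBS...` name.
#' @export
suggest_name <- function(destination, cargo, locus = NULL) {
  d <- decode_name(destination); cv <- decode_name(cargo)
  encode_name(list(prefix = "pBS", marker_digit = d$marker_digit,
                   ori_digit = d$ori_digit, cargo_digit = cv$cargo_digit,
                   bsu_marker_letter = cv$bsu_marker_letter, locus = locus))
}

#' The five-enzyme assembly set
#' @param include_btgzi keep BtgZI in the set (engine accepts it, but it is
#'   excluded from recommended defaults; see [select_enzyme()]).
#' @return character vector of enzyme names.
#' @export
assembly_enzymes <- function(include_btgzi = TRUE) {
  if (include_btgzi) c("AarI", "BtgZI", "BbsI", "BsaI", "BsmBI")
  else c("AarI", "BbsI", "BsaI", "BsmBI")
}

#' Polylinker sequence for an MCS-IIS id
#'
#' Returns the multi-enzyme polylinker realizing one side of a junction:
#' ids ending in `2` place the downstream part to the right of the junction
#' (forward orientation: recognition sites upstream of the fusion window);
#' ids ending in `1` are the mirror image for a part ending at the junction.
#' The shipped sequences are synthesized by [design_mcs_iis()] for the five
#' assembly enzymes and are synthetic stand-ins satisfying the same contract
#' as the deposited polylinkers (each enzyme excises the identical junction
#' overhang).
#'
#' @param id one of B1, B2, C1, C2, E1, E2, F1, F2.
#' @return linear [ds_seq()] with site and fusion-window features.
#' @export
mcs_iis_seq <- function(id) {
  key <- paste0("mcs_", id)
  if (!is.null(.sevaforge_env[[key]])) return(.sevaforge_env[[key]])
  fs <- fusion_sites()
  jl <- substr(id, 1, 1); side <- substr(id, 2, 2)
  i <- match(jl, fs$junction)
  if (is.na(i) || !side %in% c("1", "2")) stop("unknown MCS-IIS id: ", id)
  oh <- fs$overhang[i]
  s <- if (side == "2") design_mcs_iis(assembly_enzymes(), oh)
       else design_mcs_iis(assembly_enzymes(), oh, orientation = "reverse")
  s$id <- id
  .sevaforge_env[[key]] <- s
  s
}

#' Overhang of a junction letter
#' @param junction one of "B", "C", "E", "F".
#' @export
junction_overhang <- function(junction) {
  fs <- fusion_sites()
  i <- match(junction, fs$junction)
  if (is.na(i)) stop("unknown junction: ", junction)
  fs$overhang[i]
}

#' The vector catalog
#' @return data.frame of all registered toolbox vectors.
#' @export
list_parts <- function() load_registry()$parts
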