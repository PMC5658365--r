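#' Reading and writing sequence records
#'
#' GenBank is the canonical interchange format: the LOCUS line records the
#' topology, features are written as `misc_feature` entries with `/label`
#' qualifiers, and -- since GenBank has no native fields for them -- sticky
#' ends are stored as structured `COMMENT` lines
#' (`sevaforge-end: left|right polarity overhang`), a documented dialect
#' this package both writes and reads back losslessly.  FASTA I/O goes
#' through Biostrings; writing a molecule with sticky ends to FASTA drops
#' the end information with a warning.
#'
#' @name cli_io
NULL

#' Write a ds_seq as GenBank
#' @param seq a [ds_seq()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(seq, path) {
  if (!inherits(seq, "ds_seq")) stop("`seq` must be a ds_seq")
  name <- if (!is.null(seq$id)) gsub("\\s", "_", seq$id) else "record"
  lines <- c(sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN",
                     name, ds_length(seq), seq$topology))
  if (seq$topology == "linear") {
    lines <- c(lines,
               sprintf("COMMENT     sevaforge-end: left %s %s",
                       seq$left_end$polarity, ifelse(nzchar(seq$left_end$overhang),
                                                     seq$left_end$overhang, "-")),
               sprintf("COMMENT     sevaforge-end: right %s %s",
                       seq$right_end$polarity, ifelse(nzchar(seq$right_end$overhang),
                                                      seq$right_end$overhang, "-")))
  }
  if (!is.null(seq$role))
    lines <- c(lines, sprintf("COMMENT     sevaforge-role: %s", seq$role))
  lines <- c(lines, "FEATURES             Location/Qualifiers")
  f <- seq$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i]) # GenBank is 1-based closed
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    lines <- c(lines,
               sprintf("     misc_feature    %s", loc),
               sprintf("                     /label=\"%s\"", f$label[i]))
  }
  lines <- c(lines, "ORIGIN")
  b <- tolower(seq$bases)
  n <- nchar(b)
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substr(b, off, min(off + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", off, paste(tens, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GenBank record written in the package dialect
#' @param path GenBank file.
#' @return a [ds_seq()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  iloc <- grep("^LOCUS", lines)
  if (!length(iloc)) stop("malformed GenBank: no LOCUS line (", path, ")")
  loc <- strsplit(trimws(lines[iloc[1]]), "\\s+")[[1]]
  id <- loc[2]
  topology <- if (any(tolower(loc) == "circular")) "circular" else "linear"
  ends <- list(left = end_spec("blunt"), right = end_spec("blunt"))
  role <- NULL
  for (cl in grep("sevaforge-end:", lines, value = TRUE)) {
    p <- strsplit(trimws(sub(".*sevaforge-end:", "", cl)), "\\s+")[[1]]
    ends[[p[1]]] <- end_spec(p[2], if (p[3] == "-") "" else p[3])
  }
  rl <- grep("sevaforge-role:", lines, value = TRUE)
  if (length(rl)) role <- trimws(sub(".*sevaforge-role:", "", rl[1]))

  feats <- empty_features()
  ifeat <- grep("^\\s{5}misc_feature\\s", lines)
  for (i in ifeat) {
    locs <- trimws(sub("^\\s{5}misc_feature\\s+", "", lines[i]))
    strand <- if (startsWith(locs, "complement(")) "-" else "+"
    nums <- regmatches(locs, gregexpr("[0-9]+", locs))[[1]]
    if (length(nums) != 2L)
      stop(sprintf("malformed feature location at line %d: '%s'", i, locs))
    lab <- NA_character_
    if (i < length(lines) && grepl("/label=", lines[i + 1L])) {
      m <- regmatches(lines[i + 1L],
                      regexec("/label=\"([^\"]*)\"", lines[i + 1L]))[[1]]
      lab <- if (length(m) == 2L) m[2] else
        trimws(sub(".*/label=", "", lines[i + 1L]))
    }
    feats <- rbind(feats, data.frame(
      label = lab, start = as.integer(nums[1]) - 1L, end = as.integer(nums[2]),
      strand = strand, stringsAsFactors = FALSE))
  }
  iori <- grep("^ORIGIN", lines)
  if (!length(iori)) stop("malformed GenBank: no ORIGIN section (", path, ")")
  iend <- grep("^//", lines)
  iend <- iend[iend > iori[1]][1]
  if (is.na(iend)) stop("malformed GenBank: record not terminated with // (", path, ")")
  body <- if (iend > iori[1] + 1L) lines[(iori[1] + 1L):(iend - 1L)] else character()
  body <- sub("^\\s*[0-9]+", "", body)  # strip position numbers before filtering
  bases <- toupper(gsub("[^acgtACGT ]", "", paste(body, collapse = "")))
  bases <- gsub(" ", "", bases, fixed = TRUE)
  if (!nchar(bases)) stop("malformed GenBank: empty ORIGIN (", path, ")")
  ds_seq(bases, topology, ends$left, ends$right, features = feats,
         id = id, role = role)
}

#' Write a ds_seq as FASTA
#'
#' Sticky-end information cannot be represented in FASTA and is dropped
#' with a warning; the full-extent forward strand is written.
#' @param seq a [ds_seq()] (or list of them).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seq, path) {
  if (inherits(seq, "ds_seq")) seq <- list(seq)
  sticky <- any(vapply(seq, function(s)
    s$topology == "linear" &&
      (s$left_end$polarity != "blunt" || s$right_end$polarity != "blunt"),
    logical(1)))
  if (sticky)
    warning("FASTA cannot represent sticky ends; end information dropped")
  x <- Biostrings::DNAStringSet(vapply(seq, `[[`, character(1), "bases"))
  names(x) <- vapply(seq_along(seq), function(i)
    seq[[i]]$id %||% sprintf("record_%d", i), character(1))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read FASTA records
#' @param path FASTA file.
#' @param topology topology to assume for the records (FASTA stores none).
#' @return a [ds_seq()] if the file has one record, else a list.
#' @export
read_fasta <- function(path, topology = "linear") {
  x <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(x), function(i)
    ds_seq(as.character(x[[i]]), topology, id = names(x)[i]))
  if (length(out) == 1L) out[[1]] else out
}

#' Read a sequence record by extension
#' @param path `.gb`/`.gbk`/`.genbank` or `.fa`/`.fasta` file.
#' @param topology fallback topology for FASTA input.
#' @return a [ds_seq()].
#' @export
read_record <- function(path, topology = "linear") {
  if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE)) read_genbank(path)
  else read_fasta(path, topology)
}

#' Write a sequence record by format
#' @param seq a [ds_seq()].
#' @param path output file.
#' @param format `"genbank"` or `"fasta"`; default inferred from extension.
#' @return `path`, invisibly.
#' @export
write_record <- function(seq, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE)) "fasta"
              else "genbank"
  switch(format,
         genbank = write_genbank(seq, path),
         fasta = write_fasta(seq, path),
         stop("unknown format: ", format))
}
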