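#' @title Domain containers and file formats
#'
#' @description
#' The pipeline uses three plain `data.frame`-based containers:
#'
#' * **reference panel** (`ref_panel`): columns `id`, `taxonomy`
#'   (semicolon-joined ranked path, domain to species), `region`
#'   (`"V4"`, `"V9"` or `"SSU"`) and `sequence` (uppercase `A`/`C`/`G`/`T`/`N`).
#'   FASTA headers encode the taxonomy as `id;rank1;rank2;...`.
#' * **amplicon reads** (`amplicon_reads`): columns `id`, `sample_id`,
#'   `sequence`. FASTA headers are `id sample=<sample_id>`.
#' * **sample metadata** (`sample_metadata`): columns `sample_id`, `site`,
#'   `date` (ISO), `layer` (`surface`/`DCM`/`sediment`), `fraction`
#'   (`0.8-3`/`3-20`/`20-2000` micrometres or `none`), `template`
#'   (`DNA`/`cDNA`) and `total_reads`. Unknown columns are preserved.
#'
#' All coordinates in the package are 0-based half-open; sequences are
#' single-stranded forward.
#'
#' @name taxascreen-formats
NULL

.LAYERS <- c("surface", "DCM", "sediment")
.FRACTIONS <- c("0.8-3", "3-20", "20-2000", "none")
.TEMPLATES <- c("DNA", "cDNA")

.check_dna <- function(seq, ids, what = "sequence") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop(sprintf("non-IUPAC characters (outside A/C/G/T/N) in %s of record(s): %s",
                 what, paste(ids[bad], collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Split a semicolon-joined taxonomy path into its ranked names
#'
#' @param path character vector of `;`-joined paths.
#' @return A list of character vectors (one per path), ordered from the
#'   broadest rank to the narrowest.
#' @export
split_path <- function(path) strsplit(as.character(path), ";", fixed = TRUE)

#' Join a ranked taxonomy path into its semicolon form
#'
#' @param ranks character vector of taxon names, broadest first.
#' @return A single string.
#' @export
join_path <- function(ranks) paste(ranks, collapse = ";")

.new_ref_panel <- function(id, taxonomy, region, sequence) {
  stopifnot(!anyDuplicated(id))
  df <- data.frame(id = id, taxonomy = taxonomy, region = region,
                   sequence = sequence, stringsAsFactors = FALSE)
  class(df) <- c("ref_panel", "data.frame")
  df
}

.new_reads <- function(id, sample_id, sequence) {
  if (anyDuplicated(id))
    stop("duplicate read id(s): ",
         paste(unique(id[duplicated(id)])[1:min(5, sum(duplicated(id)))], collapse = ", "))
  df <- data.frame(id = id, sample_id = sample_id, sequence = sequence,
                   stringsAsFactors = FALSE)
  class(df) <- c("amplicon_reads", "data.frame")
  df
}

#' Read a FASTA file of references or environmental reads
#'
#' References carry their ranked taxonomy in the header
#' (`>id;rank1;rank2;...`); reads carry their sample in the header
#' (`>id sample=<sample_id>`). Lowercase bases are uppercased and gap
#' characters stripped unless `aligned = TRUE`, in which case all records must
#' have equal aligned width.
#'
#' @param path file path.
#' @param region amplicon region label attached to reference records
#'   (`"SSU"`, `"V4"` or `"V9"`).
#' @param type `"auto"` detects references (semicolon in header) versus reads
#'   (`sample=` tag); force with `"reference"` or `"reads"`.
#' @param aligned keep gap characters (`-`, `.` converted to `-`) and require
#'   equal widths.
#' @return A `ref_panel` or `amplicon_reads` data frame; for
#'   `aligned = TRUE` reference input, the gapped rows are kept in the
#'   `sequence` column. An empty file yields a zero-row object.
#' @export
read_fasta <- function(path, region = c("SSU", "V4", "V9"),
                       type = c("auto", "reference", "reads"),
                       aligned = FALSE) {
  region <- match.arg(region)
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(raw)))) {
    return(if (type == "reads") .new_reads(character(), character(), character())
           else .new_ref_panel(character(), character(), character(), character()))
  }
  first <- raw[nzchar(trimws(raw))][1]
  if (!startsWith(first, ">")) {
    stop(sprintf("malformed FASTA: line %d does not start a record ('>')",
                 which(nzchar(trimws(raw)))[1]))
  }
  x <- Biostrings::readBStringSet(path)
  headers <- names(x)
  seqs <- toupper(as.character(x))
  if (aligned) {
    seqs <- gsub(".", "-", seqs, fixed = TRUE)
    if (length(unique(nchar(seqs))) > 1)
      stop("aligned FASTA has unequal row widths")
  } else {
    seqs <- gsub("[-.]", "", seqs)
  }
  if (any(!nzchar(seqs))) {
    stop("zero-length sequence in record(s): ",
         paste(headers[!nzchar(seqs)], collapse = ", "))
  }
  if (type == "auto") {
    type <- if (any(grepl(";", headers, fixed = TRUE))) "reference" else "reads"
  }
  if (type == "reference") {
    parts <- split_path(headers)
    nrank <- lengths(parts) - 1L
    if (any(nrank < 1L)) {
      bad <- which(nrank < 1L)[1]
      stop(sprintf("malformed reference header (record %d, '%s'): expected 'id;rank1;...'",
                   bad, headers[bad]))
    }
    id <- vapply(parts, `[[`, "", 1L)
    tax <- vapply(parts, function(p) join_path(p[-1L]), "")
    .check_dna(gsub("-", "", seqs, fixed = TRUE), id)
    .new_ref_panel(id, tax, region, seqs)
  } else {
    id <- sub("\\s.*$", "", headers)
    sm <- regmatches(headers, regexpr("sample=\\S+", headers))
    has <- grepl("sample=", headers)
    sample_id <- rep(NA_character_, length(headers))
    sample_id[has] <- sub("^sample=", "", sm)
    .check_dna(gsub("-", "", seqs, fixed = TRUE), id)
    .new_reads(id, sample_id, seqs)
  }
}

#' Write references or reads to FASTA
#'
#' Inverse of [read_fasta()]: reference panels regain their
#' `id;rank1;rank2;...` headers, reads their `id sample=<sample_id>` headers.
#' Sequences are written on a single line so that a read/write round trip of
#' normalised input is byte-identical.
#'
#' @param x a `ref_panel`, `amplicon_reads`, or named character vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "ref_panel")) {
    headers <- paste(x$id, x$taxonomy, sep = ";")
    seqs <- x$sequence
  } else if (inherits(x, "amplicon_reads")) {
    headers <- paste0(x$id, " sample=", x$sample_id)
    seqs <- x$sequence
  } else {
    headers <- names(x)
    seqs <- as.character(x)
    if (is.null(headers)) stop("a plain sequence vector must be named")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs)) {
    writeLines(paste0(">", headers, "\n", seqs, collapse = "\n"), con)
  }
  invisible(path)
}

#' Read the sample metadata table
#'
#' A TSV with header row and mandatory columns `sample_id`, `site`, `date`,
#' `layer`, `fraction`, `template`, `total_reads`. Enumerated fields are
#' validated; sediment samples must have `fraction = "none"`; extra columns
#' are preserved unchanged.
#'
#' @param path TSV file path.
#' @return A `sample_metadata` data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  as_sample_metadata(df)
}

#' Validate a data frame of sample metadata
#'
#' @param df a data frame with the columns described in [read_metadata()].
#' @return A validated `sample_metadata` data frame with `total_reads`
#'   converted to integer.
#' @export
as_sample_metadata <- function(df) {
  mandatory <- c("sample_id", "site", "date", "layer", "fraction",
                 "template", "total_reads")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("metadata is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad_layer <- !(df$layer %in% .LAYERS)
  if (any(bad_layer))
    stop("invalid layer value(s): ", paste(unique(df$layer[bad_layer]), collapse = ", "),
         " (expected ", paste(.LAYERS, collapse = "/"), ")")
  bad_frac <- !(df$fraction %in% .FRACTIONS)
  if (any(bad_frac))
    stop("invalid fraction value(s): ", paste(unique(df$fraction[bad_frac]), collapse = ", "))
  bad_tmpl <- !(df$template %in% .TEMPLATES)
  if (any(bad_tmpl))
    stop("invalid template value(s): ", paste(unique(df$template[bad_tmpl]), collapse = ", "))
  sed <- df$layer == "sediment" & df$fraction != "none"
  if (any(sed))
    stop("sediment sample(s) must have fraction 'none': ",
         paste(df$sample_id[sed], collapse = ", "))
  if (any(is.na(as.Date(df$date, optional = TRUE))))
    stop("invalid ISO date(s) in metadata")
  tr <- suppressWarnings(as.integer(df$total_reads))
  if (any(is.na(tr) | tr < 0))
    stop("total_reads must be non-negative integers")
  df$total_reads <- tr
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Check that every read's sample resolves in the metadata
#'
#' Detects, at load time, reads whose `sample_id` has no metadata row, and
#' (optionally) metadata rows whose `total_reads` disagrees with the observed
#' read count.
#'
#' @param reads an `amplicon_reads` data frame.
#' @param metadata a `sample_metadata` data frame.
#' @param check_totals also require `total_reads` to equal the per-sample read
#'   count carried by `reads`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_study <- function(reads, metadata, check_totals = FALSE) {
  unresolved <- setdiff(unique(reads$sample_id), metadata$sample_id)
  if (length(unresolved))
    stop("read sample_id(s) absent from metadata: ",
         paste(unresolved, collapse = ", "))
  if (check_totals) {
    obs <- table(factor(reads$sample_id, levels = metadata$sample_id))
    bad <- metadata$total_reads != as.integer(obs)
    if (any(bad))
      stop("total_reads disagrees with observed read counts for sample(s): ",
           paste(metadata$sample_id[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' Write pipeline outputs with a checksum manifest
#'
#' Tables are written as TSV, trees as Newick; the manifest lists every file
#' with its MD5 checksum and size, and is itself written as `manifest.tsv`.
#'
#' @param tables named list of data frames / matrices (written as TSV).
#' @param trees named list of `phylo` objects (written as Newick).
#' @param dir output directory (created if necessary).
#' @return The manifest data frame (`file`, `md5`, `bytes`), invisibly.
#' @export
write_outputs <- function(tables = list(), trees = list(), dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  if (file.access(dir, 2) != 0) stop("output directory is not writable: ", dir)
  files <- character()
  for (nm in names(tables)) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    x <- tables[[nm]]
    utils::write.table(x, f, sep = "\t", quote = FALSE,
                       row.names = is.matrix(x), col.names = NA_if_matrix(x))
    files <- c(files, f)
  }
  for (nm in names(trees)) {
    f <- file.path(dir, paste0(nm, ".nwk"))
    ape::write.tree(trees[[nm]], file = f)
    files <- c(files, f)
  }
  manifest <- data.frame(
    file = basename(files),
    md5 = if (length(files)) unname(tools::md5sum(files)) else character(),
    bytes = if (length(files)) unname(file.size(files)) else numeric(),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

NA_if_matrix <- function(x) if (is.matrix(x)) NA else TRUE
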