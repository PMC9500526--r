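# Sequence and metadata input/output, grouped alignment construction.

#' @keywords internal
MT_BASES <- c("A", "C", "G", "T", "N", "-")

# Case-normalize and restrict to the 6-letter alphabet; U -> T, any other
# IUPAC ambiguity code (R, Y, S, W, ...) -> N.
normalize_bases <- function(x) {
  x[] <- toupper(x)
  x[x == "U"] <- "T"
  x[!(x %in% MT_BASES)] <- "N"
  x
}

#' Construct an alignment object
#'
#' An alignment is a set of equal-length sequences over the alphabet
#' `{A,C,G,T,N,-}`, assumed pre-aligned to a common coordinate frame
#' (typically the 16,569-site rCRS frame for human mtDNA). This constructor
#' never realigns; it only validates and normalizes.
#'
#' @param seqs Character matrix, one row per sample (rownames are sample ids),
#'   one column per site.
#' @return An object of class `mt_alignment` with fields `ids`, `seqs`
#'   (normalized character matrix) and `L` (number of sites).
#' @export
new_alignment <- function(seqs) {
  if (!is.matrix(seqs) || !is.character(seqs))
    stop("`seqs` must be a character matrix (samples x sites)")
  ids <- rownames(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("alignment rows must be named by non-empty sample ids")
  if (anyDuplicated(ids))
    stop("duplicate sample ids in alignment: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (ncol(seqs) < 1L) stop("alignment has zero sites")
  seqs <- normalize_bases(seqs)
  structure(list(ids = ids, seqs = seqs, L = ncol(seqs)),
            class = "mt_alignment")
}

#' Read an aligned FASTA file
#'
#' Reads a multi-record FASTA file of pre-aligned sequences. Characters are
#' case-normalized, `U` is mapped to `T`, and any IUPAC ambiguity code other
#' than `N` is stored as `N`.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return An [new_alignment()] object.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e)
      stop("not a readable FASTA file: ", path, " (",
           conditionMessage(e), ")", call. = FALSE))
  if (length(recs) == 0L) stop("FASTA file contains no records: ", path)
  lens <- Biostrings::width(recs)
  if (length(unique(lens)) != 1L)
    stop("records are not aligned to a common length (lengths: ",
         paste(sort(unique(lens)), collapse = ", "), ")")
  seqs <- do.call(rbind, strsplit(as.character(recs), "", fixed = TRUE))
  rownames(seqs) <- sub("\\s.*$", "", names(recs))   # id = first header token
  new_alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' One record per sample, sequence on a single line, preserving record order.
#' A read-write-read round trip preserves ids, order and sequences exactly.
#'
#' @param aln An `mt_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "mt_alignment"))
  lines <- character(2L * length(aln$ids))
  lines[c(TRUE, FALSE)] <- paste0(">", aln$ids)
  lines[c(FALSE, TRUE)] <- apply(aln$seqs, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.mt_alignment <- function(x, ...) {
  cat("mt_alignment:", length(x$ids), "sequences x", x$L, "sites\n")
  invisible(x)
}

subset_alignment <- function(aln, ids) {
  miss <- setdiff(ids, aln$ids)
  if (length(miss))
    stop("ids not in alignment: ", paste(miss, collapse = ", "))
  new_alignment(aln$seqs[ids, , drop = FALSE])
}

default_schema <- c(id = "sample_id", group = "group", site = "locality",
                    culture_period = "culture_period", date = "date",
                    haplogroup = "haplogroup")

#' Read a per-sample metadata table
#'
#' Reads delimited metadata (CSV with header) into a `sample_table` with the
#' canonical fields `id`, `group`, `site`, `culture_period`, `date`,
#' `haplogroup` and a derived `age_BP` column (see [parse_age_bp()]).
#' Missing optional columns yield `NA` fields.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector remapping canonical field names to
#'   column names in the file, e.g. `c(id = "Sample id", site = "Locality")`.
#'   Unmentioned fields use the defaults `sample_id`, `group`, `locality`,
#'   `culture_period`, `date`, `haplogroup`.
#' @return A data frame of class `sample_table`.
#' @export
read_metadata <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sch <- default_schema
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), names(sch))
    if (length(bad)) stop("unknown schema field(s): ", paste(bad, collapse = ", "))
    sch[names(schema)] <- schema
  }
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!sch[["id"]] %in% names(raw))
    stop("id column '", sch[["id"]], "' not found in ", path)
  id <- trimws(raw[[sch[["id"]]]])
  if (anyDuplicated(id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  grab <- function(field) {
    col <- sch[[field]]
    if (col %in% names(raw)) {
      v <- trimws(raw[[col]])
      v[!nzchar(v)] <- NA_character_
      v
    } else rep(NA_character_, nrow(raw))
  }
  out <- data.frame(id = id,
                    group = grab("group"),
                    site = grab("site"),
                    culture_period = grab("culture_period"),
                    date = grab("date"),
                    haplogroup = grab("haplogroup"),
                    stringsAsFactors = FALSE)
  out$age_BP <- parse_age_bp(out$date)
  class(out) <- c("sample_table", "data.frame")
  out
}

#' Convert a printed date estimate to years before present
#'
#' Documented rule: a BCE interval "X–Y BCE" (optionally "cal. BCE", with or
#' without thousands separators) maps to its midpoint plus 1950; a single
#' year "X BCE" to X + 1950; "Nth cen. BCE" to the century midpoint
#' (100·N − 50) + 1950; "X BP" passes through. Empty or unrecognized strings
#' give `NA` (with a warning for the unrecognized).
#'
#' @param x Character vector of date strings.
#' @return Numeric vector of ages in years BP (present = 1950 CE).
#' @export
parse_age_bp <- function(x) {
  out <- rep(NA_real_, length(x))
  if (!length(x)) return(out)
  s <- ifelse(is.na(x), "", trimws(x))
  s <- gsub(",", "", s)                         # thousands separators
  s <- gsub("cal\\.?\\s*", "", s, ignore.case = TRUE)
  dash <- "[-–—]"
  re_range  <- paste0("^([0-9]+)\\s*", dash, "\\s*([0-9]+)\\s*BCE$")
  re_cent   <- "^([0-9]+)(st|nd|rd|th)\\s*cen\\.?\\s*BCE$"
  re_single <- "^([0-9]+)\\s*BCE$"
  re_bp     <- "^([0-9]+)\\s*BP$"
  bad <- character(0)
  for (i in seq_along(s)) {
    v <- s[i]
    if (!nzchar(v)) next
    if (grepl(re_range, v)) {
      a <- as.numeric(sub(re_range, "\\1", v))
      b <- as.numeric(sub(re_range, "\\2", v))
      out[i] <- (a + b) / 2 + 1950
    } else if (grepl(re_cent, v, ignore.case = TRUE)) {
      cn <- as.numeric(sub(re_cent, "\\1", v, ignore.case = TRUE))
      out[i] <- (100 * cn - 50) + 1950
    } else if (grepl(re_single, v)) {
      out[i] <- as.numeric(sub(re_single, "\\1", v)) + 1950
    } else if (grepl(re_bp, v)) {
      out[i] <- as.numeric(sub(re_bp, "\\1", v))
    } else {
      bad <- c(bad, x[i])
    }
  }
  if (length(bad))
    warning("unparseable date string(s) set to NA: ",
            paste(unique(bad), collapse = "; "))
  out
}

#' Partition an alignment into named groups
#'
#' Builds a grouped alignment from an alignment and a metadata table, using
#' one metadata column as the grouping label (e.g. locality-by-culture).
#' Metadata rows whose id has no alignment record are excluded with a
#' warning; alignment records absent from the table are simply left
#' unassigned (the partition may cover a subset of the alignment).
#'
#' @param alignment An `mt_alignment`.
#' @param table A `sample_table` (or any data frame with `id` and the
#'   grouping column; an `age_BP` column is carried over when present).
#' @param group_field Name of the grouping column. Default `"group"`.
#' @return An object of class `grouped_alignment`: list with `alignment`,
#'   `partition` (named list of id vectors, each group non-empty) and `ages`
#'   (named numeric, years BP, `NA` when unknown).
#' @export
build_grouped <- function(alignment, table, group_field = "group") {
  stopifnot(inherits(alignment, "mt_alignment"))
  if (!group_field %in% names(table))
    stop("grouping column '", group_field, "' not present in metadata")
  g <- as.character(table[[group_field]])
  has_group <- !is.na(g) & nzchar(g)
  if (!any(has_group)) stop("grouping column '", group_field, "' is empty")
  in_aln <- table$id %in% alignment$ids
  dropped <- has_group & !in_aln
  if (any(dropped))
    warning(sum(dropped), " metadata row(s) have no alignment record and ",
            "were excluded: ",
            paste(utils::head(table$id[dropped], 5L), collapse = ", "),
            if (sum(dropped) > 5L) ", ..." else "")
  use <- has_group & in_aln
  if (!any(use)) stop("empty partition: no grouped metadata id matches the alignment")
  partition <- split(table$id[use], g[use])
  ages <- if ("age_BP" %in% names(table))
    stats::setNames(as.numeric(table$age_BP[use]), table$id[use])
  else
    stats::setNames(rep(NA_real_, sum(use)), table$id[use])
  structure(list(alignment = alignment, partition = partition, ages = ages),
            class = "grouped_alignment")
}

#' @export
print.grouped_alignment <- function(x, ...) {
  cat("grouped_alignment:", length(x$partition), "groups over",
      length(x$alignment$ids), "sequences x", x$alignment$L, "sites\n")
  sizes <- vapply(x$partition, length, integer(1))
  cat(paste0("  ", names(sizes), " (n=", sizes, ")", collapse = "\n"), "\n")
  invisible(x)
}

group_sizes <- function(ga) vapply(ga$partition, length, integer(1))

# Character submatrix of one group's sequences.
group_matrix <- function(ga, group) {
  ids <- ga$partition[[group]]
  if (is.null(ids)) stop("no such group: ", group)
  ga$alignment$seqs[ids, , drop = FALSE]
}
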