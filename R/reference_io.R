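#' Read a FASTA file of reference sequences
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that normalises
#' sequences to uppercase and strips gap characters and whitespace, returning
#' a plain data frame. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` (first whitespace-delimited token of
#'   the header) and `sequence` (uppercase DNA string).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  seqs <- toupper(gsub("[-. \t]", "", as.character(set)))
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write reference sequences to FASTA
#'
#' @param records Data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a reference taxonomy table
#'
#' The taxonomy TSV has a header row and columns `id`, `lineage`
#' (semicolon-joined ranks, phylum through genus; missing ranks may be empty
#' strings), `role` (strictly `producer` or `consumer`) and `diazotroph`
#' (`true`/`false`). Lines starting with `#` are ignored.
#'
#' Producers are the autotrophic taxa (Cyanobacteria and chemoautotrophs);
#' consumers are all heterotrophic bacteria. The role vocabulary is strict:
#' any other token is an error rather than silently coerced.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `id`, `lineage`, `role`, `diazotroph`.
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("id", "lineage", "role", "diazotroph")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("taxonomy table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate taxonomy id(s): ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  bad_role <- setdiff(unique(tab$role), c("producer", "consumer"))
  if (length(bad_role)) {
    stop("unknown role token(s): ", paste(bad_role, collapse = ", "),
         " (allowed: producer, consumer)")
  }
  bad_dz <- !tolower(tab$diazotroph) %in% c("true", "false")
  if (any(bad_dz)) stop("diazotroph column must be true/false")
  tab$diazotroph <- tolower(tab$diazotroph) == "true"
  tab[, required]
}

#' Write a taxonomy table
#' @param taxonomy Data frame as returned by [read_taxonomy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  out <- taxonomy
  out$diazotroph <- ifelse(out$diazotroph, "true", "false")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a validated reference library
#'
#' Joins sequences and taxonomy into one table and enforces the reference
#' invariants: every sequence record has a taxonomy row, sequences contain
#' only A/C/G/T/N (ambiguity codes other than N are rejected in references,
#' though they are preserved in reads), and every lineage has at least one
#' non-empty rank.
#'
#' @param records Data frame from [read_fasta()].
#' @param taxonomy Data frame from [read_taxonomy()].
#' @return Data frame with columns `id`, `sequence`, `lineage`, `role`,
#'   `diazotroph`.
#' @export
reference_library <- function(records, taxonomy) {
  missing <- setdiff(records$id, taxonomy$id)
  if (length(missing)) {
    stop("no taxonomy for reference(s): ", paste(missing, collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", records$sequence)
  if (any(bad)) {
    stop("reference sequence(s) with ambiguity codes other than N: ",
         paste(records$id[bad], collapse = ", "))
  }
  tax <- taxonomy[match(records$id, taxonomy$id), ]
  no_rank <- !vapply(strsplit(tax$lineage, ";", fixed = TRUE),
                     function(r) any(nzchar(r)), logical(1))
  if (any(no_rank)) {
    stop("empty lineage for: ", paste(tax$id[no_rank], collapse = ", "))
  }
  data.frame(id = records$id, sequence = records$sequence,
             lineage = tax$lineage, role = tax$role,
             diazotroph = tax$diazotroph, stringsAsFactors = FALSE)
}

#' Read a FASTQ file (phred+33)
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return Data frame with columns `id`, `sequence`, and `qualities` (a list
#'   column of integer phred scores, one per base).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) | seq_along(lines) %% 4L != 0L]
  if (length(lines) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      qualities = I(list()), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record at end of '", path, "'")
  }
  idx <- seq(1L, length(lines), by = 4L)
  heads <- lines[idx]
  if (any(substr(heads, 1L, 1L) != "@")) {
    stop("malformed FASTQ header at record ",
         which(substr(heads, 1L, 1L) != "@")[1])
  }
  ids <- sub("^@", "", vapply(strsplit(heads, "[ \t]+"), `[[`, character(1), 1L))
  seqs <- toupper(lines[idx + 1L])
  quals <- lines[idx + 3L]
  qlist <- lapply(quals, function(q) as.integer(charToRaw(q)) - 33L)
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad)) {
    stop("sequence/quality length mismatch for read(s): ",
         paste(ids[bad], collapse = ", "))
  }
  rng <- range(unlist(qlist, use.names = FALSE))
  if (rng[1] < 0 || rng[2] > 60) {
    stop("phred scores outside [0, 60]; is the file phred+33?")
  }
  data.frame(id = ids, sequence = seqs, qualities = I(qlist),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (phred+33)
#' @param reads Data frame as returned by [read_fastq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(reads$qualities,
                 function(q) rawToChar(as.raw(q + 33L)), character(1))
  out <- as.vector(rbind(paste0("@", reads$id), reads$sequence, "+", qual))
  writeLines(out, path)
  invisible(path)
}

#' Read site metadata
#'
#' Site metadata TSV with columns `site_id`, `koppen` (one of EF, ET, BWk,
#' BWh, Af), `map_mm` (mean annual precipitation, mm/yr), `tmin_c`, `tmax_c`
#' (minimum winter / maximum summer temperature, degrees C) and
#' `growing_season_d` (days per year when temperature, moisture and light
#' jointly permit photosynthesis, 0-366).
#'
#' @param path Path to the TSV file.
#' @return Validated data frame.
#' @export
read_metadata <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("site_id", "koppen", "map_mm", "tmin_c", "tmax_c",
                "growing_season_d")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  }
  bad_k <- setdiff(unique(tab$koppen), c("EF", "ET", "BWk", "BWh", "Af"))
  if (length(bad_k)) stop("unknown Koppen class(es): ",
                          paste(bad_k, collapse = ", "))
  if (any(tab$map_mm < 0)) stop("map_mm must be >= 0")
  if (any(tab$tmax_c < tab$tmin_c)) stop("tmax_c must be >= tmin_c")
  if (any(tab$growing_season_d < 0 | tab$growing_season_d > 366)) {
    stop("growing_season_d must lie in [0, 366]")
  }
  tab[, required]
}
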