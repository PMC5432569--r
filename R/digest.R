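# IUPAC expansion sets used for degenerate primer and recognition-site
# matching. N in a subject sequence never satisfies a recognition site
# (handled in find_cut_positions by requiring concrete bases).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Restriction enzymes with a built-in catalogue
#'
#' An enzyme is described by its recognition site (IUPAC DNA) and the 0-based
#' offset of the cut within the site: MspI cuts C^CGG (offset 1), HaeIII
#' GG^CC (offset 2), HinfI G^ANTC (offset 1).
#'
#' @param name One of `"MspI"`, `"HaeIII"`, `"HinfI"`, or any name when
#'   `recognition` and `cut_offset` are supplied.
#' @param recognition IUPAC recognition sequence (overrides the catalogue).
#' @param cut_offset Integer in `[0, nchar(recognition)]`; the cut falls
#'   before this 0-based position within the site.
#' @return A list with elements `name`, `recognition`, `cut_offset`.
#' @export
enzyme <- function(name, recognition = NULL, cut_offset = NULL) {
  catalogue <- list(
    MspI   = list(recognition = "CCGG",  cut_offset = 1L),
    HaeIII = list(recognition = "GGCC",  cut_offset = 2L),
    HinfI  = list(recognition = "GANTC", cut_offset = 1L)
  )
  if (is.null(recognition)) {
    if (!name %in% names(catalogue)) {
      stop("unknown enzyme '", name, "'; supply recognition and cut_offset")
    }
    recognition <- catalogue[[name]]$recognition
    cut_offset <- catalogue[[name]]$cut_offset
  }
  recognition <- toupper(recognition)
  if (!all(strsplit(recognition, "")[[1]] %in% names(IUPAC_SETS))) {
    stop("recognition site contains non-IUPAC characters")
  }
  if (cut_offset < 0 || cut_offset > nchar(recognition)) {
    stop("cut_offset must lie in [0, site length]")
  }
  list(name = name, recognition = recognition, cut_offset = as.integer(cut_offset))
}

#' Default 16S rRNA primer pair (341F / 907R)
#'
#' Both primers are given 5'-3'. The forward primer carries the fluorescent
#' label; the reverse primer is matched on the template as its reverse
#' complement. 907R contains the degenerate base M (A/C).
#'
#' @param forward Forward primer sequence.
#' @param reverse Reverse primer sequence.
#' @return List with elements `forward`, `reverse`.
#' @export
primer_pair <- function(forward = "CCTACGGGAGGCAGCAG",
                        reverse = "CCGTCAATTCMTTTGAGTTT") {
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (!nzchar(forward) || !nzchar(reverse)) stop("primers must be non-empty")
  list(forward = forward, reverse = reverse)
}

#' Does an IUPAC code match a concrete base?
#'
#' @param code A single IUPAC DNA code.
#' @param base A concrete base, one of A, C, G, T.
#' @return `TRUE` iff `base` lies in the expansion set of `code`.
#' @export
iupac_match <- function(code, base) {
  code <- toupper(code); base <- toupper(base)
  if (is.null(IUPAC_SETS[[code]])) stop("invalid IUPAC code: ", code)
  if (!base %in% c("A", "C", "G", "T")) stop("base must be one of A,C,G,T")
  base %in% IUPAC_SETS[[code]]
}

#' Reverse complement of an IUPAC DNA string
#' @param seq DNA string (IUPAC codes allowed).
#' @return Reverse complement string.
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(seq))
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# All start positions (1-based) where `pattern` (IUPAC) matches `seq` with at
# most max_mismatch mismatches. A subject base matches a pattern position iff
# it lies in the IUPAC expansion of the pattern code; subject bases outside
# A/C/G/T never match. Vectorised over offsets within the pattern.
iupac_match_positions <- function(seq, pattern, max_mismatch = 0L) {
  n <- nchar(seq); m <- nchar(pattern)
  if (m == 0L || n < m) return(integer(0))
  sc <- strsplit(toupper(seq), "")[[1]]
  pc <- strsplit(toupper(pattern), "")[[1]]
  if (any(!pc %in% names(IUPAC_SETS))) stop("pattern contains non-IUPAC characters")
  n_start <- n - m + 1L
  mism <- integer(n_start)
  for (j in seq_len(m)) {
    ok <- sc[j:(j + n_start - 1L)] %in% IUPAC_SETS[[pc[j]]]
    mism <- mism + !ok
  }
  which(mism <= max_mismatch)
}

#' Find the leftmost primer match in a sequence
#'
#' Degenerate primer positions match per IUPAC expansion; the primer is
#' matched on the given strand. Positions are 1-based.
#'
#' @param seq Subject DNA string.
#' @param primer Primer sequence (IUPAC).
#' @param max_mismatch Maximum tolerated mismatches (default 0).
#' @return 1-based start position of the leftmost match, or `NA_integer_`.
#' @export
find_primer <- function(seq, primer, max_mismatch = 0L) {
  hits <- iupac_match_positions(seq, primer, max_mismatch)
  if (length(hits)) hits[1L] else NA_integer_
}

#' Extract the PCR amplicon delimited by a primer pair
#'
#' The amplicon spans from the start of the leftmost forward-primer match to
#' the end of the first reverse-primer site downstream of it (the reverse
#' primer is matched as its reverse complement), both annealing sites
#' included — the shortest product, which dominates in PCR.
#'
#' @param seq Reference DNA string.
#' @param primers A [primer_pair()].
#' @param max_mismatch Mismatches tolerated per primer.
#' @return Amplicon substring, or `NA_character_` if either site is absent or
#'   the reverse site lies upstream of the forward site.
#' @export
extract_amplicon <- function(seq, primers = primer_pair(), max_mismatch = 0L) {
  f <- find_primer(seq, primers$forward, max_mismatch)
  if (is.na(f)) return(NA_character_)
  rc <- revcomp(primers$reverse)
  r_hits <- iupac_match_positions(seq, rc, max_mismatch)
  r_hits <- r_hits[r_hits >= f + nchar(primers$forward)]
  if (!length(r_hits)) return(NA_character_)
  substr(seq, f, r_hits[1L] + nchar(rc) - 1L)
}

#' Find restriction cut positions in a concrete sequence
#'
#' Returns between-base cut coordinates: a value of `p` means the enzyme cuts
#' after the p-th nucleotide. Overlapping recognition sites are all reported.
#' Subject bases outside A/C/G/T (including N) never satisfy a recognition
#' site.
#'
#' @param seq Concrete DNA string.
#' @param enz An [enzyme()].
#' @return Strictly ascending integer vector of cut coordinates.
#' @export
find_cut_positions <- function(seq, enz) {
  starts <- iupac_match_positions(seq, enz$recognition, 0L)
  sort(starts - 1L + enz$cut_offset)
}

#' Terminal restriction fragment of a labeled amplicon
#'
#' The terminal restriction fragment (TRF) runs from the 5' labeled
#' (forward-primer) end of the amplicon to the first restriction cut; its
#' length is the first cut coordinate. An amplicon without a recognition site
#' yields an uncut labeled fragment of full amplicon length, flagged
#' `no_site`.
#'
#' @param amplicon Amplicon DNA string (5' end = labeled end).
#' @param enz An [enzyme()].
#' @return List with `trf_bp` (integer length) and `no_site` (logical).
#' @export
terminal_fragment <- function(amplicon, enz) {
  if (is.na(amplicon) || !nzchar(amplicon)) stop("empty amplicon")
  cuts <- find_cut_positions(amplicon, enz)
  cuts <- cuts[cuts >= 1L]          # a cut at coordinate 0 frees no labeled base
  if (length(cuts)) {
    list(trf_bp = cuts[1L], no_site = FALSE)
  } else {
    list(trf_bp = nchar(amplicon), no_site = TRUE)
  }
}

#' Virtual restriction digest of a reference library
#'
#' For every reference sequence, extracts the primer-delimited amplicon and
#' predicts the terminal restriction fragment length under the given enzyme.
#' References in which either primer site is absent are excluded and
#' reported.
#'
#' @param refs Data frame with columns `id`, `sequence`; extra columns
#'   (`lineage`, `role`, `diazotroph`) are carried through.
#' @param primers A [primer_pair()].
#' @param enz An [enzyme()] (default MspI).
#' @param max_mismatch Primer mismatches tolerated (default 0).
#' @return List with `table` (data frame: `id`, `trf_bp`, `no_site`, plus
#'   carried columns) and `excluded` (character vector of reference ids with
#'   no amplicon).
#' @export
virtual_digest <- function(refs, primers = primer_pair(), enz = enzyme("MspI"),
                           max_mismatch = 0L) {
  amplicons <- vapply(refs$sequence, extract_amplicon, character(1),
                      primers = primers, max_mismatch = max_mismatch,
                      USE.NAMES = FALSE)
  usable <- !is.na(amplicons)
  if (!any(usable)) stop("no reference yields an amplicon with these primers")
  frag <- lapply(amplicons[usable], terminal_fragment, enz = enz)
  tab <- data.frame(
    id = refs$id[usable],
    trf_bp = vapply(frag, `[[`, integer(1), "trf_bp"),
    no_site = vapply(frag, `[[`, logical(1), "no_site"),
    stringsAsFactors = FALSE
  )
  for (col in intersect(c("lineage", "role", "diazotroph"), names(refs))) {
    tab[[col]] <- refs[[col]][usable]
  }
  list(table = tab, excluded = refs$id[!usable])
}
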