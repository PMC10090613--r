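# Characters accepted in input sequences. Ambiguity codes are kept verbatim
# but treated as missing data downstream (see pairwise_differences).
DNA_BASES <- c("A", "C", "G", "T")
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
ALLOWED_CHARS <- c(DNA_BASES, IUPAC_AMBIG, "-", "?")

MARKERS <- c("cox1", "ITS2", "28S", "other")

#' Construct a sequence set or alignment
#'
#' A `seq_set` holds named DNA sequences for one marker. When all sequences
#' have equal length the object is "alignment-capable" and gains class
#' `"alignment"`; all distance and tree operations require an alignment.
#'
#' Residues are stored uppercase; `U` is normalized to `T` on construction so
#' ribosomal markers supplied as RNA are processed in DNA space.
#'
#' @param seqs named character vector of residue strings. Names are sequence
#'   ids and must be unique and non-empty.
#' @param marker one of `"cox1"`, `"ITS2"`, `"28S"`, `"other"`.
#' @return an object of class `c("alignment", "seq_set")` if all sequences
#'   share one length, otherwise class `"seq_set"`.
#' @examples
#' aln <- seq_set(c(A = "ACGT", B = "ACGA"), marker = "cox1")
#' aln_length(aln)
#' @export
seq_set <- function(seqs, marker = "other") {
  marker <- match.arg(marker, MARKERS)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids))
    stop("all sequences must have non-empty ids")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(seqs) == 0L) stop("empty sequence set")
  seqs <- toupper(seqs)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    length(ch) == 0L || !all(ch %in% ALLOWED_CHARS)
  }, logical(1))
  if (any(bad))
    stop("invalid or empty residues in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  lens <- nchar(seqs)
  obj <- structure(
    list(ids = ids, seqs = unname(seqs), marker = marker,
         lengths = unname(lens)),
    class = "seq_set"
  )
  if (length(unique(lens)) == 1L) {
    class(obj) <- c("alignment", "seq_set")
    obj$length <- lens[[1L]]
  }
  obj
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("<%s> %d sequences, marker %s",
              if (inherits(x, "alignment")) "alignment" else "seq_set",
              length(x$ids), x$marker))
  if (inherits(x, "alignment")) cat(sprintf(", %d columns", x$length))
  cat("\n")
  invisible(x)
}

#' @rdname seq_set
#' @param x a `seq_set`
#' @export
is_alignment <- function(x) inherits(x, "alignment")

#' @rdname seq_set
#' @export
aln_length <- function(x) {
  if (!is_alignment(x)) stop("sequences are not aligned (unequal lengths)")
  x$length
}

#' Alignment as a character matrix
#'
#' Rows are sequences (named by id), columns are alignment positions.
#' @param x an `alignment`
#' @return character matrix of single characters
#' @export
aln_matrix <- function(x) {
  if (!is_alignment(x)) stop("sequences are not aligned (unequal lengths)")
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' Build an alignment from a character matrix
#' @param m character matrix with unique rownames
#' @param marker marker label
#' @export
aln_from_matrix <- function(m, marker = "other") {
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- rownames(m)
  seq_set(seqs, marker = marker)
}

#' Read sequences from a FASTA file
#'
#' Parsing is done by [Biostrings::readBStringSet()]; this wrapper validates
#' ids (non-empty, unique), residues, and flags the result as an alignment
#' when all sequences share one length. Header descriptions after the first
#' whitespace are dropped from the id but a record such as
#' `">id some description"` is accepted.
#'
#' @param path FASTA file path
#' @param marker marker label attached to the result
#' @return `seq_set` (or `alignment` when alignment-capable)
#' @export
read_fasta <- function(path, marker = "other") {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("FASTA parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (length(ss) == 0L) stop("FASTA parse error: no records in ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(ids))) {
    bad <- which(!nzchar(ids))
    stop("FASTA parse error: empty header at record ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  empty <- Biostrings::width(ss) == 0L
  if (any(empty))
    stop("FASTA parse error: empty record at index ",
         paste(which(empty), collapse = ", "))
  seqs <- as.character(ss)
  names(seqs) <- ids
  seq_set(seqs, marker = marker)
}

#' Write sequences to a FASTA file
#'
#' Wraps [Biostrings::writeXStringSet()] with 70-column line wrapping.
#' Round-trip property: `read_fasta(write_fasta(x, f))` reproduces ids and
#' residues exactly.
#'
#' @param x a `seq_set`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "seq_set"))
  ss <- Biostrings::BStringSet(x$seqs)
  names(ss) <- x$ids
  tryCatch(Biostrings::writeXStringSet(ss, path, width = 70L),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

# Standard genetic code, codon order TTT, TTC, TTA, ... (T,C,A,G nesting).
STANDARD_AA <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  "")[[1]]

#' Genetic code tables
#'
#' Returns the codon-to-amino-acid map for NCBI translation table 1
#' (standard) or 9 (echinoderm/flatworm mitochondrial). Table 9 differs from
#' the standard code at AAA (Asn, not Lys), AGA and AGG (Ser, not Arg) and
#' TGA (Trp, not stop). The tables are embedded, not fetched.
#'
#' @param table_id 1 or 9
#' @return named character vector mapping all 64 codons to one-letter amino
#'   acids, `"*"` for stop; class `"genetic_code"`.
#' @export
genetic_code <- function(table_id = 9L) {
  bases <- c("T", "C", "A", "G")
  # codons in T,C,A,G nesting: first base slowest, third fastest
  codons <- apply(expand.grid(b3 = bases, b2 = bases, b1 = bases)[, 3:1], 1L,
                  paste, collapse = "")
  map <- STANDARD_AA
  names(map) <- codons
  if (table_id == 9L) {
    map[c("AAA", "AGA", "AGG", "TGA")] <- c("N", "S", "S", "W")
  } else if (table_id != 1L) {
    stop("unsupported translation table: ", table_id)
  }
  structure(map, table_id = as.integer(table_id), class = "genetic_code")
}

#' Translate a nucleotide sequence
#'
#' Gaps are not allowed; codons containing non-ACGT characters translate to
#' `"X"`. Trailing partial codons are dropped.
#'
#' @param residues residue string (no gaps)
#' @param code a [genetic_code()]
#' @param frame 0, 1 or 2 (offset in bases)
#' @return character vector of amino acids
#' @export
translate_frame <- function(residues, code = genetic_code(9L), frame = 0L) {
  s <- strsplit(toupper(residues), "", fixed = TRUE)[[1]]
  if (any(s == "-")) stop("gaps present; strip gaps before translation")
  s <- s[(frame + 1L):length(s)]
  n_codon <- length(s) %/% 3L
  if (n_codon == 0L) return(character(0))
  s <- s[seq_len(n_codon * 3L)]
  cod <- apply(matrix(s, nrow = 3L), 2L, paste, collapse = "")
  aa <- unname(code[cod])
  aa[is.na(aa)] <- "X"
  aa
}

#' Scan reading frames for internal stop codons
#'
#' Mitochondrial barcode quality check: a protein-coding fragment in correct
#' orientation should have at least one forward frame free of internal stop
#' codons under the organismal genetic code. Gaps are stripped first. A stop
#' in the final (possibly terminal) codon of a frame is not counted as
#' internal. Reverse-complement frames are only scanned when
#' `reverse = TRUE`, as barcodes are conventionally deposited in coding
#' orientation.
#'
#' @param residues residue string (gaps allowed; stripped)
#' @param code a [genetic_code()]
#' @param reverse also scan the three reverse-complement frames
#' @return list with per-frame stop counts/positions (codon indices) and
#'   `any_open`: whether some scanned frame is internal-stop-free
#' @export
scan_reading_frames <- function(residues, code = genetic_code(9L),
                                reverse = FALSE) {
  s0 <- gsub("-", "", toupper(residues), fixed = TRUE)
  if (nchar(s0) < 3L) stop("fewer than 3 bases after gap stripping")
  scan1 <- function(seqstr, frame) {
    aa <- translate_frame(seqstr, code, frame)
    internal <- if (length(aa) > 1L) which(aa[-length(aa)] == "*") else integer(0)
    list(frame = frame, n_codons = length(aa),
         n_internal_stops = length(internal), stop_positions = internal)
  }
  frames <- lapply(0:2, function(f) scan1(s0, f))
  if (reverse) {
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s0, "")[[1]]), collapse = ""))
    frames <- c(frames, lapply(0:2, function(f) {
      r <- scan1(rc, f); r$frame <- paste0("rev", f); r
    }))
  }
  structure(list(
    frames = frames,
    any_open = any(vapply(frames, function(f) f$n_internal_stops == 0L,
                          logical(1)))
  ), class = "frame_report")
}

#' @export
print.frame_report <- function(x, ...) {
  for (f in x$frames)
    cat(sprintf("frame %s: %d codons, %d internal stop(s)\n",
                f$frame, f$n_codons, f$n_internal_stops))
  cat(if (x$any_open) "at least one frame is internal-stop-free\n"
      else "no internal-stop-free frame\n")
  invisible(x)
}
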