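#' @useDynLib taarminer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET  <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Standard genetic code keyed by codon; codons containing N translate to "X".
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  as.list(gc)
})

.complement_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.check_dna <- function(dna) {
  if (length(dna) != 1L || !is.character(dna))
    stop("DNA sequence must be a single character string")
  bad <- setdiff(unique(strsplit(dna, "", fixed = TRUE)[[1]]), DNA_ALPHABET)
  if (length(bad))
    stop("invalid DNA characters: ", paste(bad, collapse = ", "))
  invisible(dna)
}

#' Translate a coding sequence
#'
#' Translates DNA to protein under the standard genetic code. Codons
#' containing \code{N} give \code{X}; stop codons give \code{*}.
#'
#' @param dna A single DNA string over \code{A,C,G,T,N}; its length must be a
#'   multiple of 3.
#' @return A single amino-acid string, one residue per codon.
#' @examples
#' translate_cds("ATGTTTAGA")  # "MFR"
#' @export
translate_cds <- function(dna) {
  .check_dna(dna)
  n <- nchar(dna)
  if (n %% 3L != 0L)
    stop("malformed CDS: length ", n, " is not a multiple of 3")
  if (n == 0L) return("")
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  # codons absent from the table are those containing N
  out <- character(length(codons))
  hit <- match(codons, names(.codon_table))
  out[!is.na(hit)] <- unlist(.codon_table[codons[!is.na(hit)]], use.names = FALSE)
  out[is.na(hit)] <- "X"
  paste(out, collapse = "")
}

#' Reverse complement
#'
#' @param dna A DNA string over \code{A,C,G,T,N} (\code{N} self-complements).
#' @return The reverse complement string.
#' @export
reverse_complement <- function(dna) {
  .check_dna(dna)
  if (nchar(dna) == 0L) return("")
  chars <- strsplit(dna, "", fixed = TRUE)[[1]]
  paste(rev(.complement_map[chars]), collapse = "")
}

#' Six-frame translation of a contig
#'
#' Translates both strands in all three frames, dropping trailing partial
#' codons, and records the coordinate offset needed to map protein positions
#' back to the forward-strand contig.
#'
#' @param seq Contig DNA string.
#' @param id Contig identifier carried through to hits.
#' @return A list of six elements (frames \code{+1,+2,+3,-1,-2,-3}), each with
#'   \code{frame}, \code{strand}, \code{offset} (0-based offset of the frame's
#'   first base on its own strand) and \code{protein}.
#' @seealso [frame_interval()] for the inverse coordinate map.
#' @export
six_frame_translate <- function(seq, id = "contig") {
  .check_dna(seq)
  n <- nchar(seq)
  if (n < 3L) {
    warning("contig '", id, "' shorter than 3 nt: no frames")
    return(list())
  }
  rc <- reverse_complement(seq)
  out <- vector("list", 6L)
  k <- 1L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (off in 0:2) {
      ncod <- (n - off) %/% 3L
      prot <- if (ncod > 0L)
        translate_cds(substr(s, off + 1L, off + 3L * ncod)) else ""
      out[[k]] <- list(contig_id = id,
                       frame = if (strand == "+") off + 1L else -(off + 1L),
                       strand = strand, offset = off,
                       contig_length = n, protein = prot)
      k <- k + 1L
    }
  }
  out
}

#' Map a protein position in a frame back to genomic coordinates
#'
#' @param frame One element of the [six_frame_translate()] result.
#' @param aa_start,aa_end 1-based inclusive residue positions in the frame
#'   protein.
#' @return A list with \code{start}, \code{end} (0-based half-open, forward
#'   strand) and \code{strand}; the interval spans exactly
#'   \code{3 * (aa_end - aa_start + 1)} nt.
#' @export
frame_interval <- function(frame, aa_start, aa_end = aa_start) {
  stopifnot(aa_start >= 1L, aa_end >= aa_start)
  s0 <- frame$offset + 3L * (aa_start - 1L)        # on the frame's own strand
  e0 <- frame$offset + 3L * aa_end
  if (frame$strand == "+") {
    list(start = s0, end = e0, strand = "+")
  } else {
    n <- frame$contig_length
    list(start = n - e0, end = n - s0, strand = "-")
  }
}

#' Read a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file. Lowercase is uppercased;
#'   \code{U} is rejected (DNA/protein only).
#' @param type \code{"DNA"} or \code{"AA"}; controls alphabet validation.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA")
    Biostrings::readBStringSet(path) else Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(seqs) <- ids
  if (type == "DNA") {
    if (any(grepl("U", seqs, fixed = TRUE)))
      stop("RNA-like 'U' characters found; DNA input required")
    for (s in seqs) .check_dna(s)
  }
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path. Sequences are wrapped at 60 columns.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, n)), con)
  }
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon/CDS rows with 1-based inclusive coordinates, phase 0
#' CDS (all introns are phase 0), and \code{status} / \code{junction}
#' attributes in column 9.
#'
#' @param models A list of gene models as built by the gene-model stage.
#' @param path Output path.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (gm in models) {
    exons <- gm$exons
    g1 <- min(vapply(exons, `[[`, 0, "start")) + 1L
    g2 <- max(vapply(exons, `[[`, 0, "end"))
    attrs <- sprintf("ID=%s;status=%s", gm$name, gm$status)
    if (!is.null(gm$junction))
      attrs <- paste0(attrs, ";junction=", gm$junction)
    base <- function(type, s, e, ph, att)
      sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              gm$contig_id, "taarminer", type, s, e, gm$strand, ph, att)
    writeLines(base("gene", g1, g2, ".", attrs), con)
    writeLines(base("mRNA", g1, g2, ".",
                    sprintf("ID=%s.t1;Parent=%s", gm$name, gm$name)), con)
    for (k in seq_along(exons)) {
      ex <- exons[[k]]
      writeLines(base("exon", ex$start + 1L, ex$end, ".",
                      sprintf("ID=%s.e%d;Parent=%s.t1", gm$name, k, gm$name)), con)
      writeLines(base("CDS", ex$start + 1L, ex$end, "0",
                      sprintf("ID=%s.c%d;Parent=%s.t1", gm$name, k, gm$name)), con)
    }
  }
  invisible(path)
}

# substring on the forward strand, returned on `strand`
# (start/end are 0-based half-open forward coordinates)
.extract_strand <- function(seq, start, end, strand) {
  s <- substr(seq, start + 1L, end)
  if (strand == "-") reverse_complement(s) else s
}
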