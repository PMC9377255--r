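#' Amino-acid alphabet accepted in catalogs
#'
#' The 20 canonical residues plus `X` (unknown). Ambiguity codes `B`, `J`,
#' `O`, `U`, `Z` and `*` are rejected at read time.
#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

validate_protein_seq <- function(seq, id) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0) {
    stop("invalid residue(s) ", paste(bad, collapse = ", "),
         " in record '", id, "'")
  }
  invisible(TRUE)
}

#' Read a protein catalog from FASTA
#'
#' One `ProteinRecord` row per entry, in file order. Description lines are
#' split at the first whitespace: the first token is the id, the remainder
#' is kept as free-text description. Sequences are uppercased; only the 20
#' canonical residues plus `X` are accepted.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return a `data.frame` with columns `id`, `seq`, `length`, `desc`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", basename(path), ": ",
                             conditionMessage(e))
  )
  if (length(set) == 0) {
    warning("empty FASTA file: ", basename(path))
    return(data.frame(id = character(), seq = character(),
                      length = integer(), desc = character(),
                      stringsAsFactors = FALSE))
  }
  full <- names(set)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(id)) {
    stop("duplicate id(s) in ", basename(path), ": ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  seq <- unname(toupper(as.character(set)))
  if (any(nchar(seq) == 0)) {
    stop("empty sequence for record '", id[which(nchar(seq) == 0)[1]], "'")
  }
  Map(validate_protein_seq, seq, id)
  data.frame(id = id, seq = seq, length = nchar(seq), desc = desc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a protein catalog to FASTA
#'
#' @param catalog data.frame with `id`, `seq` (and optionally `desc`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(catalog, path) {
  nm <- catalog$id
  if (!is.null(catalog$desc)) {
    has <- !is.na(catalog$desc) & nzchar(catalog$desc)
    nm[has] <- paste(catalog$id[has], catalog$desc[has])
  }
  set <- Biostrings::BStringSet(setNames(catalog$seq, nm))
  Biostrings::writeXStringSet(set, path, width = 80)
  invisible(path)
}
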