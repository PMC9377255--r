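#' Structural classes of gut microbial GUS enzymes
#'
#' Loop 1, mini-Loop 1, Loop 2, mini-Loop 2, mini-Loop 1,2, No Loop,
#' FMN-binding and No Coverage, in the fixed order used for deterministic
#' tie-breaking.
#' @export
GUS_CLASSES <- c("L1", "mL1", "L2", "mL2", "mL1_2", "NL", "FMN", "NC")

#' Read a representative GUS reference set
#'
#' A representative set is a FASTA of amino-acid sequences plus a TSV
#' annotation with one row per representative:
#' \describe{
#'   \item{id}{matches the FASTA id}
#'   \item{gus_class}{one of [GUS_CLASSES]}
#'   \item{taxonomy}{source organism label}
#'   \item{catalytic}{exactly 7 comma-separated `position:residue` pairs,
#'     1-based, e.g. `"210:N,212:K,..."`}
#'   \item{loop1_start,loop1_end,loop2_start,loop2_end}{closed 1-based
#'     intervals marking the loop-1 and loop-2 regions}
#'   \item{fmn_start,fmn_end}{closed interval of the C-terminal FMN-binding
#'     segment, `.` for non-FMN representatives}
#' }
#'
#' Validation enforces that every annotated catalytic residue letter matches
#' the sequence at its index.
#'
#' @param fasta_path,tsv_path paths to the two files.
#' @return a list of representative records (class `gus_representatives`),
#'   each with `id`, `seq`, `gus_class`, `taxonomy`, `cat_pos` (integer 7),
#'   `cat_res` (character 7), `loop1`, `loop2`, `fmn` (integer 2 or `NULL`).
#' @export
read_representatives <- function(fasta_path, tsv_path) {
  fa <- read_protein_fasta(fasta_path)
  ann <- read_table(tsv_path,
                    required = c("id", "gus_class", "taxonomy", "catalytic",
                                 "loop1_start", "loop1_end",
                                 "loop2_start", "loop2_end"),
                    numeric_cols = c("loop1_start", "loop1_end",
                                     "loop2_start", "loop2_end",
                                     "fmn_start", "fmn_end"))
  if (!all(ann$id %in% fa$id)) {
    stop("annotation ids missing from FASTA: ",
         paste(setdiff(ann$id, fa$id), collapse = ", "))
  }
  reps <- lapply(seq_len(nrow(ann)), function(i) {
    row <- ann[i, ]
    seq <- fa$seq[match(row$id, fa$id)]
    pairs <- strsplit(strsplit(row$catalytic, ",", fixed = TRUE)[[1]], ":",
                      fixed = TRUE)
    if (length(pairs) != 7) {
      stop("representative '", row$id, "' must have exactly 7 catalytic ",
           "positions, got ", length(pairs))
    }
    pos <- vapply(pairs, function(p) as.integer(p[1]), integer(1))
    res <- vapply(pairs, function(p) p[2], character(1))
    if (any(pos < 1) || any(pos > nchar(seq))) {
      stop("catalytic position outside sequence for '", row$id, "'")
    }
    actual <- substring(seq, pos, pos)
    if (!all(actual == res)) {
      stop("catalytic residue mismatch for '", row$id, "' at position ",
           pos[which(actual != res)[1]])
    }
    if (!row$gus_class %in% GUS_CLASSES) {
      stop("unknown gus_class '", row$gus_class, "' for '", row$id, "'")
    }
    fmn <- NULL
    if (!is.null(row$fmn_start) && !is.na(row$fmn_start)) {
      fmn <- c(as.integer(row$fmn_start), as.integer(row$fmn_end))
    }
    list(id = row$id, seq = seq, gus_class = row$gus_class,
         taxonomy = row$taxonomy, cat_pos = pos, cat_res = res,
         loop1 = c(as.integer(row$loop1_start), as.integer(row$loop1_end)),
         loop2 = c(as.integer(row$loop2_start), as.integer(row$loop2_end)),
         fmn = fmn)
  })
  names(reps) <- ann$id
  structure(reps, class = "gus_representatives")
}

#' Load the bundled synthetic representative set
#'
#' Seventeen synthetic representative GUS sequences spanning the structural
#' classes, with annotated catalytic heptads, loop windows and FMN
#' C-terminal segments. These are generated stand-ins with the same
#' annotation structure as a curated crystal-structure reference set; they
#' are intended for simulation and testing, not for screening real
#' catalogs.
#'
#' @return a `gus_representatives` list of length 17.
#' @export
load_default_representatives <- function() {
  read_representatives(
    system.file("extdata", "synthetic_representatives.faa",
                package = "gusome", mustWork = TRUE),
    system.file("extdata", "synthetic_representatives.tsv",
                package = "gusome", mustWork = TRUE)
  )
}

#' @export
print.gus_representatives <- function(x, ...) {
  cat(sprintf("%d representative GUS sequences (%s)\n", length(x),
              paste(sort(unique(vapply(x, `[[`, "", "gus_class"))),
                    collapse = ", ")))
  invisible(x)
}
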