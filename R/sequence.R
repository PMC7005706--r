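# Capped peptide sequences: parsing, formatting, molecular weights.

#' Parse a capped peptide sequence
#'
#' Accepts the conventional capped notation, e.g. `"Ac-SSFPQPN-NH2"`,
#' `"Ac-Pro-Phe-Ser-Pro-Phe-Ser-Pro-Phe-NH2"`, or a bare body
#' (`"SSFPQPN"`).  The leading `Ac-` marks an N-terminal acetyl cap and a
#' trailing `-NH2` (or `-CONH2`) a C-terminal amide; both default to free
#' termini when absent.  Bodies may be one-letter strings or
#' hyphen-separated three-letter codes.
#'
#' @param text Sequence string.
#' @return An object of class `peptide_sequence`: list with `residues`
#'   (one-letter codes, N to C), `n_cap` (`"Ac"` or `"free"`), `c_cap`
#'   (`"NH2"` or `"free"`).
#' @examples
#' s7 <- parse_capped_sequence("Ac-SSFPQPN-NH2")
#' length(s7$residues) # 7
#' @export
parse_capped_sequence <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("sequence must be a single character string", call. = FALSE)
  raw <- trimws(text)
  if (nchar(raw) == 0L) stop("empty sequence", call. = FALSE)

  n_cap <- "free"; c_cap <- "free"
  body <- raw
  if (grepl("^[Aa][Cc]-", body)) {
    n_cap <- "Ac"
    body <- sub("^[Aa][Cc]-", "", body)
  }
  if (grepl("-(NH2|CONH2)$", body, ignore.case = TRUE)) {
    c_cap <- "NH2"
    body <- sub("-(NH2|CONH2)$", "", body, ignore.case = TRUE)
  }
  if (nchar(body) == 0L) stop("empty sequence body", call. = FALSE)

  tokens <- if (grepl("-", body, fixed = TRUE)) {
    strsplit(body, "-", fixed = TRUE)[[1]]
  } else if (grepl("^[A-Z][a-z]{2}$", body)) {
    body # a single unhyphenated three-letter code ("Ser")
  } else {
    strsplit(body, "")[[1]]
  }
  residues <- vapply(tokens, .normalize_code, character(1), USE.NAMES = FALSE)

  structure(list(residues = residues, n_cap = n_cap, c_cap = c_cap),
            class = "peptide_sequence")
}

#' Format a capped sequence back to its text form
#'
#' Inverse of [parse_capped_sequence()] (one-letter body).
#' @param seq A `peptide_sequence`.
#' @param three_letter Use hyphenated three-letter codes for the body.
#' @return Character scalar such as `"Ac-SSFPQPN-NH2"`.
#' @export
format_sequence <- function(seq, three_letter = FALSE) {
  stopifnot(inherits(seq, "peptide_sequence"))
  body <- if (three_letter) {
    paste(.one_to_three[seq$residues], collapse = "-")
  } else {
    paste(seq$residues, collapse = "")
  }
  out <- body
  if (seq$n_cap == "Ac") out <- paste0("Ac-", out)
  if (seq$c_cap == "NH2") out <- paste0(out, "-NH2")
  out
}

#' @export
print.peptide_sequence <- function(x, ...) {
  cat("<peptide_sequence> ", format_sequence(x), "  (",
      length(x$residues), " residues, N-cap: ", x$n_cap,
      ", C-cap: ", x$c_cap, ")\n", sep = "")
  invisible(x)
}

#' Average molecular weight of a capped peptide
#'
#' Sum of average residue masses plus one water, an acetyl cap adding
#' C2H2O (+42.04 Da) and a C-terminal amide replacing OH by NH2
#' (-0.98 Da).  Average (not monoisotopic) atomic weights are used,
#' matching how peptide vendors report masses.
#'
#' Note: for the two published 8-mers the printed masses are mutually
#' swapped relative to their sequences -- Ac-PFSPFSPF-NH2 (3 Pro, 3 Phe,
#' 2 Ser) computes to ~966.10 Da and Ac-FSFSFSFS-NH2 (4 Phe, 4 Ser) to
#' ~996.09 Da.  This function always computes from the sequence.
#'
#' @param seq A `peptide_sequence` or a sequence string.
#' @return Mass in Da.
#' @examples
#' molecular_weight("Ac-SSFPQPN-NH2") # 816.87
#' @export
molecular_weight <- function(seq) {
  if (is.character(seq)) seq <- parse_capped_sequence(seq)
  stopifnot(inherits(seq, "peptide_sequence"))
  m <- sum(.residue_masses[seq$residues]) + .mass_water
  if (seq$n_cap == "Ac") m <- m + .mass_acetyl_delta
  if (seq$c_cap == "NH2") m <- m + .mass_amide_delta
  unname(m)
}
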