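.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single character string")
  res <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(unique(res), .AA1)
  if (length(bad))
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  res
}

#' Lubricin mucin-domain model peptide sequence
#'
#' Residues 393-410 of human lubricin (PRG4), spanning one KEPAPTTP tandem
#' repeat and its most common variant KEPAPTTT. This is the default peptide
#' for all worked examples in the package.
#'
#' @format A single string, "PKEPAPTTTKEPAPTTPK".
#' @export
mucin_peptide_sequence <- "PKEPAPTTTKEPAPTTPK"

#' Assign O-glycosylation sites on a mucin peptide
#'
#' Mucin-domain O-linked glycans (GalNAc-Gal) attach to threonines. This
#' returns every threonine position in the peptide's residue numbering,
#' minus an explicit exclusion set; in lubricin's 393-410 model peptide the
#' third threonine (Thr401) is known to be unglycosylated and is excluded.
#'
#' @param sequence One-letter amino-acid string.
#' @param first_residue_number Residue number of the first residue
#'   (default 1; the lubricin model peptide starts at 393).
#' @param exclude Integer vector of residue numbers that must not receive a
#'   glycan. Each must lie inside the peptide's numbering range and point at
#'   a threonine.
#' @return Sorted integer vector of glycosylated residue numbers.
#' @examples
#' assign_glyco_sites("PKEPAPTTTKEPAPTTPK", 393, exclude = 401)
#' @export
assign_glyco_sites <- function(sequence, first_residue_number = 1L,
                               exclude = integer()) {
  res <- .check_sequence(sequence)
  if (length(res) == 0L) stop("sequence must be non-empty")
  nums <- seq_along(res) + as.integer(first_residue_number) - 1L
  exclude <- as.integer(exclude)
  if (length(exclude)) {
    out_of_range <- exclude[exclude < nums[1L] | exclude > nums[length(nums)]]
    if (length(out_of_range))
      stop("excluded residue number(s) outside peptide range: ",
           paste(out_of_range, collapse = ", "))
    not_thr <- exclude[res[match(exclude, nums)] != "T"]
    if (length(not_thr))
      stop("excluded residue number(s) are not threonine: ",
           paste(not_thr, collapse = ", "))
  }
  sort(setdiff(nums[res == "T"], exclude))
}

#' Count residues with high polyproline-II propensity
#'
#' Proline has the highest intrinsic PPII propensity; alanine and residues
#' with long linear side chains such as lysine also rank high. With the
#' default set \{P, A, K\}, five of the eight residues of the KEPAPTTP
#' mucin tandem repeat count as high-propensity.
#'
#' @param sequence One-letter amino-acid string (may be empty).
#' @param high_propensity Character vector of one-letter codes treated as
#'   high-PPII-propensity residue types.
#' @return Integer count.
#' @examples
#' count_high_ppii_residues("KEPAPTTP")
#' @export
count_high_ppii_residues <- function(sequence, high_propensity = c("P", "A", "K")) {
  if (identical(sequence, "")) return(0L)
  res <- .check_sequence(sequence)
  bad <- setdiff(high_propensity, .AA1)
  if (length(bad))
    stop("unknown residue letter(s) in high_propensity: ",
         paste(bad, collapse = ", "))
  sum(res %in% high_propensity)
}

#' Construct a mucin-domain peptide model
#'
#' Bundles a peptide sequence with its residue numbering, O-glycosylation
#' site flags and a per-residue backbone dihedral assignment
#' (phi, psi, omega). The default assignment puts every residue in the
#' canonical polyproline-II conformation (-75, 145) with trans peptide
#' bonds (omega = 180), the initial conformation used for mucin-domain
#' model building.
#'
#' @param sequence One-letter amino-acid string.
#' @param first_residue_number Number of the first residue (default 1).
#' @param glyco_sites Integer vector of glycosylated residue numbers; each
#'   must be a threonine or serine. Glycans are represented as site flags
#'   only, never as atoms.
#' @param phi,psi,omega Per-residue dihedral assignment in degrees;
#'   recycled to the sequence length. omega defaults to 180 (trans).
#' @return An object of class \code{peptide_model} with fields
#'   \code{sequence}, \code{residues} (data frame: number, type,
#'   glycosylated) and \code{dihedrals} (data frame: phi, psi, omega).
#' @examples
#' peptide_model(mucin_peptide_sequence, 393,
#'               glyco_sites = assign_glyco_sites(mucin_peptide_sequence,
#'                                                393, exclude = 401))
#' @export
peptide_model <- function(sequence, first_residue_number = 1L,
                          glyco_sites = integer(),
                          phi = -75, psi = 145, omega = 180) {
  res <- .check_sequence(sequence)
  n <- length(res)
  if (n == 0L) stop("sequence must be non-empty")
  nums <- seq_len(n) + as.integer(first_residue_number) - 1L
  glyco_sites <- as.integer(glyco_sites)
  if (length(glyco_sites)) {
    if (any(glyco_sites < nums[1L] | glyco_sites > nums[n]))
      stop("glyco_sites outside the peptide numbering range")
    types <- res[match(glyco_sites, nums)]
    if (any(!types %in% c("T", "S")))
      stop("glyco_sites must point at threonine or serine residues")
  }
  dih <- data.frame(residue_number = nums,
                    phi = wrap180(rep_len(phi, n)),
                    psi = wrap180(rep_len(psi, n)),
                    omega = wrap180(rep_len(omega, n)))
  structure(list(
    sequence = sequence,
    residues = data.frame(number = nums, type = res,
                          glycosylated = nums %in% glyco_sites),
    dihedrals = dih
  ), class = "peptide_model")
}

#' @export
print.peptide_model <- function(x, ...) {
  n <- nrow(x$residues)
  cat("peptide_model:", x$sequence, "\n")
  cat("  residues", x$residues$number[1L], "-", x$residues$number[n],
      sprintf("(%d residues)\n", n))
  gl <- x$residues$number[x$residues$glycosylated]
  cat("  O-glycosylation sites:",
      if (length(gl)) paste(gl, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Preset lubricin mucin-domain model peptides
#'
#' Convenience constructors for the two systems the package's analyses
#' revolve around: the 18-mer lubricin mucin-domain subsection (residues
#' 393-410) and the threonine tetrapeptide TTTT, each in glycosylated or
#' non-glycosylated form. Glycosylation of the 18-mer covers four of its
#' five threonines (Thr401 is excluded); the tetrapeptide is glycosylated
#' on every threonine.
#'
#' @param glycosylated Logical; attach glycan site flags?
#' @return A \code{peptide_model}.
#' @export
mucin_model <- function(glycosylated = FALSE) {
  sites <- if (glycosylated)
    assign_glyco_sites(mucin_peptide_sequence, 393L, exclude = 401L)
  else integer()
  peptide_model(mucin_peptide_sequence, 393L, glyco_sites = sites)
}

#' @rdname mucin_model
#' @export
tttt_model <- function(glycosylated = FALSE) {
  sites <- if (glycosylated) assign_glyco_sites("TTTT", 1L) else integer()
  peptide_model("TTTT", 1L, glyco_sites = sites)
}
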