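#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

# Fixed one-letter amino-acid ordering used by all 20-column tables.
AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

# Kyte-Doolittle hydropathy scale (kcal/mol-free units, range -4.5..4.5).
KD_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
                   G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
                   M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
                   S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

#' Amino-acid alphabet used by scanning tables
#'
#' Returns the fixed 20-letter one-letter amino-acid ordering used for the
#' rows/columns of every 20-wide table in the package (mutational scan
#' tables, pair potentials, substitution similarities).
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() AA_ORDER

#' Convert between three-letter and one-letter residue codes
#'
#' @param x character vector of residue codes.
#' @return Character vector; `NA` for non-standard residues.
#' @export
aa_three_to_one <- function(x) {
  out <- unname(AA_ONE[toupper(x)])
  out
}

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) unname(AA_THREE[toupper(x)])

#' Is a residue name one of the 20 standard amino acids?
#'
#' @param x character vector of three-letter residue names.
#' @return Logical vector.
#' @export
is_standard_residue <- function(x) toupper(x) %in% AA_THREE

#' Default residue-residue contact potential
#'
#' Loads the package's built-in 20x20 pairwise contact energy table
#' (kcal/mol), a simple hydrophobic contact potential derived from the
#' Kyte-Doolittle hydropathy scale: with h' the hydropathy rescaled to
#' \[0, 1\], e(a, b) = -h'(a) h'(b), so contacts between hydrophobic
#' residues are favourable (negative) and losing them on mutation is
#' destabilizing (positive score). The table is symmetric and shipped as
#' plain CSV under `inst/extdata`.
#'
#' @return Symmetric 20x20 numeric matrix with dimnames [aa_alphabet()].
#' @export
default_pair_potential <- function() {
  path <- system.file("extdata", "contact_potential_kd.csv",
                      package = "allonet", mustWork = TRUE)
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE,
                                 comment.char = "#"))
  storage.mode(m) <- "double"
  m[AA_ORDER, AA_ORDER]
}

#' Default substitution similarity table
#'
#' Builds the 20x20 similarity table s(a, b) in \[0, 1\] used by the
#' reweight perturbation mode, from the BLOSUM62 log-odds matrix shipped
#' with Biostrings via the normalized-odds transform
#' s(a, b) = 2^(B(a,b)/2) / sqrt(2^(B(a,a)/2) * 2^(B(b,b)/2)),
#' clamped to \[0, 1\]. The diagonal is exactly 1 and the table is
#' symmetric, so a wild-type "substitution" leaves edge couplings
#' untouched while dissimilar substitutions shrink them most.
#'
#' @return An object of class `SubstitutionSimilarity`: a 20x20 numeric
#'   matrix with attribute `source`.
#' @export
default_similarity <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  b <- e$BLOSUM62[AA_ORDER, AA_ORDER]
  odds <- 2^(b / 2)
  d <- sqrt(diag(odds))
  s <- odds / outer(d, d)
  s <- pmin(pmax(s, 0), 1)
  diag(s) <- 1
  s <- (s + t(s)) / 2
  substitution_similarity(s, source = "BLOSUM62 normalized odds")
}

#' Construct a substitution-similarity table
#'
#' @param s 20x20 numeric matrix, rows/cols in [aa_alphabet()] order or
#'   named; values in \[0, 1\], symmetric, unit diagonal.
#' @param source short label recording where the table came from.
#' @return `SubstitutionSimilarity` object.
#' @export
substitution_similarity <- function(s, source = "user") {
  s <- as.matrix(s)
  if (!is.null(rownames(s))) s <- s[AA_ORDER, AA_ORDER]
  stopifnot(nrow(s) == 20L, ncol(s) == 20L)
  if (max(abs(s - t(s))) > 1e-12)
    stop("similarity table must be symmetric")
  if (any(abs(diag(s) - 1) > 1e-12))
    stop("similarity table diagonal must be exactly 1")
  if (any(s < 0 | s > 1)) stop("similarity values must lie in [0, 1]")
  dimnames(s) <- list(AA_ORDER, AA_ORDER)
  structure(s, source = source, class = c("SubstitutionSimilarity", "matrix"))
}
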