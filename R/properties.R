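# Physicochemical property tables backing PAAC and CTD.

#' Chou's three classical PAAC properties (raw values)
#'
#' Hydrophobicity, hydrophilicity and side-chain mass for the 20 standard
#' residues, in the alphabetical order of [AA_ALPHABET]. These are the
#' canonical tables of Chou's pseudo amino acid composition; they are
#' standardized (zero mean, unit population sd over the 20 residues) before
#' use.
#'
#' @return A 3 x 20 numeric matrix, rows `hydrophobicity`, `hydrophilicity`,
#'   `side_chain_mass`, columns named by residue.
#' @export
chou_properties <- function() {
  hydrophobicity <- c(
    A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
    H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
    P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
    W = 0.81, Y = 0.26)
  hydrophilicity <- c(
    A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0,
    H = -0.5, I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2,
    P = 0.0, Q = 0.2, R = 3.0, S = 0.3, T = -0.4, V = -1.5,
    W = -3.4, Y = -2.3)
  side_chain_mass <- c(
    A = 15, C = 47, D = 59, E = 73, F = 91, G = 1,
    H = 82, I = 57, K = 73, L = 57, M = 75, N = 58,
    P = 42, Q = 72, R = 101, S = 31, T = 45, V = 43,
    W = 130, Y = 107)
  rbind(hydrophobicity = hydrophobicity[AA_ALPHABET],
        hydrophilicity = hydrophilicity[AA_ALPHABET],
        side_chain_mass = side_chain_mass[AA_ALPHABET])
}

# Standardize each row to zero mean and unit *population* sd over the 20
# residues (Chou's convention; denominator 20, not 19).
standardize_properties <- function(m) {
  t(apply(m, 1L, function(v) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) stop("constant property vector cannot be standardized")
    (v - mean(v)) / s
  }))
}

#' PAAC parameters
#'
#' @param lambda number of sequence-order correlation tiers (>= 1).
#' @param weight weight of the pseudo components (> 0); Chou's default 0.05.
#' @param properties raw per-residue property matrix (rows = properties,
#'   columns = the 20 residues in [AA_ALPHABET] order); standardized
#'   internally.
#' @return A `paac_params` object with the standardized property matrix.
#' @export
paac_params <- function(lambda = 1L, weight = 0.05,
                        properties = chou_properties()) {
  lambda <- as.integer(lambda)
  stopifnot(lambda >= 1L, weight > 0, is.matrix(properties),
            ncol(properties) == 20L)
  colnames(properties) <- AA_ALPHABET
  std <- standardize_properties(properties)
  structure(list(lambda = lambda, weight = weight, properties = std),
            class = "paac_params")
}

#' One CTD attribute grouping
#'
#' @param attribute attribute name.
#' @param groups list of exactly three non-empty character vectors of
#'   residues, together covering all 20 standard residues exactly once.
#' @return A `ctd_grouping` object with a residue-to-group lookup.
#' @export
ctd_grouping <- function(attribute, groups) {
  stopifnot(is.character(attribute), length(groups) == 3L)
  all_res <- unlist(groups)
  if (length(all_res) != 20L || anyDuplicated(all_res) ||
      !setequal(all_res, AA_ALPHABET)) {
    stop("groups must partition the 20 standard residues")
  }
  if (any(lengths(groups) == 0L)) stop("all three groups must be non-empty")
  group_of <- integer(20L)
  names(group_of) <- AA_ALPHABET
  for (g in 1:3) group_of[groups[[g]]] <- g
  structure(list(attribute = attribute, groups = groups,
                 group_of = group_of),
            class = "ctd_grouping")
}

#' The default CTD attribute set (Dubchak-style, seven attributes)
#'
#' Each attribute partitions the 20 residues into three groups:
#' hydrophobicity (polar / neutral / hydrophobic), normalized van der Waals
#' volume, polarity, polarizability, charge (positive / neutral / negative),
#' secondary-structure propensity (helix / strand / coil), and solvent
#' accessibility (buried / exposed / intermediate). Seven attributes of
#' 21 features each give the 147-dimensional default CTD encoding.
#'
#' @return A named list of seven [ctd_grouping()] objects.
#' @export
ctd_groupings <- function() {
  spl <- function(...) lapply(list(...), function(s) strsplit(s, "")[[1L]])
  list(
    hydrophobicity = ctd_grouping("hydrophobicity",
      spl("RKEDQN", "GASTPHY", "CLVIMFW")),
    vdw_volume = ctd_grouping("vdw_volume",
      spl("GASCTPD", "NVEQIL", "MHKFRYW")),
    polarity = ctd_grouping("polarity",
      spl("LIFWCMVY", "PATGS", "HQRKNED")),
    polarizability = ctd_grouping("polarizability",
      spl("GASDT", "CPNVEQIL", "KMHFRYW")),
    charge = ctd_grouping("charge",
      spl("KR", "ANCQGHILMFPSTWYV", "DE")),
    secondary_structure = ctd_grouping("secondary_structure",
      spl("EALMQKRH", "VIYCWFT", "GNPSD")),
    solvent_accessibility = ctd_grouping("solvent_accessibility",
      spl("ALFCGIVW", "RKQEND", "MPSTHY")))
}
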