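# Residue metadata: chi counts, chi-defining quadruples (IUPAC), code maps,
# idealized backbone geometry used by the chain builder and the relaxer.

.aaChiCount <- c(
  ALA = 0L, GLY = 0L, SER = 1L, THR = 1L, VAL = 1L, CYS = 1L,
  ASP = 2L, ASN = 2L, HIS = 2L, ILE = 2L, LEU = 2L, PHE = 2L, PRO = 2L,
  TRP = 2L, TYR = 2L, MET = 3L, GLU = 3L, GLN = 3L, ARG = 4L, LYS = 4L
)

.threeToOne <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

.oneToThree <- structure(names(.threeToOne), names = unname(.threeToOne))

# chi_k is torsion over the last atom listed here preceded by the three
# before it in the path N-CA-CB-G-D-E-Z
.chiPathAtoms <- list(
  ARG = c("CG", "CD", "NE", "CZ"), LYS = c("CG", "CD", "CE", "NZ"),
  MET = c("CG", "SD", "CE"), GLU = c("CG", "CD", "OE1"),
  GLN = c("CG", "CD", "OE1"),
  ASP = c("CG", "OD1"), ASN = c("CG", "OD1"), HIS = c("CG", "ND1"),
  ILE = c("CG1", "CD1"), LEU = c("CG", "CD1"), PHE = c("CG", "CD1"),
  PRO = c("CG", "CD"), TRP = c("CG", "CD1"), TYR = c("CG", "CD1"),
  SER = "OG", THR = "OG1", VAL = "CG1", CYS = "SG",
  ALA = character(0), GLY = character(0)
)

# full quadruple of atom names defining chi_k for a residue type
.chiQuadruple <- function(resName, k) {
  path <- c("N", "CA", "CB", .chiPathAtoms[[resName]])
  if (k + 3 > length(path)) return(NULL)
  path[k:(k + 3)]
}

# idealized backbone geometry (Angstrom, degrees); the peptide C-N bond is
# built at the reference mean length so freshly built chains carry a zero
# bond-length z-score
.backboneGeom <- list(
  bNCa = 1.458, bCaC = 1.525, bCN = 1.348, bCO = 1.229,
  aNCaC = 111.2, aCaCN = 116.2, aCNCa = 121.7, aCaCO = 120.8
)

# default side-chain rotamers used when a torsion spec does not give chis;
# proline uses its ring-consistent template values
.defaultChis <- function(resName) {
  n <- .aaChiCount[[resName]]
  if (n == 0L) return(numeric(0))
  if (resName == "PRO") return(c(23.8, 0.0))
  chi <- c(-65, 180, 180, 180)[seq_len(n)]
  if (resName %in% c("PHE", "TYR", "TRP", "HIS")) chi[1:2] <- c(180, 90)
  if (resName %in% c("ASP", "ASN")) chi[2] <- -20
  chi
}

#' Default van der Waals radii (Bondi)
#'
#' Element-to-radius mapping used by the clash counter and the repulsion term
#' of the relaxation protocol. The Bondi set is used: C 1.70, N 1.55, O 1.52,
#' S 1.80 Angstrom.
#'
#' @return named numeric vector of radii in Angstrom.
#' @export
defaultVdwTable <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
}
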