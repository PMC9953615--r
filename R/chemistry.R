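#' @keywords internal
"_PACKAGE"

## Residue chemistry tables used across the coarse-grained model.

# gas constant, kcal/mol/K
.RGAS <- 0.0019872041
# ln(10); the "2.3" prefactor of the pKa free-energy relations
.LN10 <- log(10)

# default aqueous reference pKas of the ionizable side chains
.PKA_W <- c(ASP = 4.0, GLU = 4.4, HIS = 6.5, LYS = 10.5, ARG = 12.5)

# sign of the ionized form: +1 bases, -1 acids
.ION_SIGN <- c(ASP = -1, GLU = -1, HIS = +1, LYS = +1, ARG = +1)

# side chains counted as polar in environment classification
# (ionizables are polar as well)
.POLAR_SET <- c("SER", "THR", "ASN", "GLN", "TYR", "HIS", "CYS",
                "ASP", "GLU", "LYS", "ARG")

# atoms of the ionizable functional group (used to shift the side-chain
# interaction centre X toward the charged moiety)
.ION_GROUP <- list(
  ASP = c("OD1", "OD2", "CG"),
  GLU = c("OE1", "OE2", "CD"),
  LYS = "NZ",
  ARG = c("NE", "CZ", "NH1", "NH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# effective side-chain contact radii (A) for the 8-6 pair potential;
# one value per residue class, summed over the pair
.VDW_R0 <- c(
  GLY = 2.0, ALA = 2.2, SER = 2.2, CYS = 2.4, THR = 2.4, PRO = 2.4,
  VAL = 2.5, ASN = 2.5, ASP = 2.4, ILE = 2.7, LEU = 2.7, MET = 2.7,
  GLU = 2.6, GLN = 2.6, LYS = 2.7, HIS = 2.7, ARG = 2.9, PHE = 2.9,
  TYR = 2.9, TRP = 3.1
)
.VDW_R0_DEFAULT <- 2.5

# backbone partial charges (e) approximating the main-chain dipoles for
# the charge-dipole term of the binding potential; net zero per residue
.BB_DIPOLE_Q <- c(N = -0.30, CA = 0.30, C = 0.45, O = -0.45)

.is_ionizable <- function(resid, ionizable_set = names(.PKA_W)) {
  toupper(resid) %in% ionizable_set
}

.is_polar <- function(resid) toupper(resid) %in% .POLAR_SET

.pka_w_of <- function(resid, pka_table = .PKA_W) {
  unname(pka_table[toupper(resid)])
}

.ion_sign_of <- function(resid) {
  s <- .ION_SIGN[toupper(resid)]
  if (any(is.na(s))) stop("no ionization sign for residue(s): ",
                          paste(resid[is.na(s)], collapse = ", "))
  unname(s)
}
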