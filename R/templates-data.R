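# Auto-generated ideal-geometry side-chain templates (CCD ideal coordinates).
# Each residue: data.frame(atom, element, dref, aref, parent, length, angle,
#   dihtype ('chi' or 'fixed'), chik, dihval) where torsion(dref,aref,parent,atom)
#   = chi_k + dihval for dihtype 'chi', or = dihval for 'fixed'.
.sidechainTemplates <- list(
  ALA = data.frame(
    atom = c("CB"),
    element = c("C"),
    dref = c("C"),
    aref = c("N"),
    parent = c("CA"),
    length = c(1.5294),
    angle = c(109.465),
    dihtype = c("fixed"),
    chik = c(0L),
    dihval = c(119.999),
    stringsAsFactors = FALSE
  ),
  ARG = data.frame(
    atom = c("CB","CG","CD","NE","CZ","NH1","NH2"),
    element = c("C","C","C","N","C","N","N"),
    dref = c("C","N","CA","CB","CG","CD","CD"),
    aref = c("N","CA","CB","CG","CD","NE","NE"),
    parent = c("CA","CB","CG","CD","NE","CZ","CZ"),
    length = c(1.5363,1.5371,1.5273,1.4435,1.4058,1.3906,1.3912),
    angle = c(111.550,114.536,112.417,111.016,123.005,120.996,119.815),
    dihtype = c("fixed","chi","chi","chi","chi","fixed","fixed"),
    chik = c(0L,1L,2L,3L,4L,0L,0L),
    dihval = c(123.561,0.000,0.000,0.000,0.000,-179.986,0.012),
    stringsAsFactors = FALSE
  ),
  ASN = data.frame(
    atom = c("CB","CG","OD1","ND2"),
    element = c("C","C","O","N"),
    dref = c("C","N","CA","CA"),
    aref = c("N","CA","CB","CB"),
    parent = c("CA","CB","CG","CG"),
    length = c(1.5309,1.5066,1.2133,1.3476),
    angle = c(109.454,109.484,119.974,120.012),
    dihtype = c("fixed","chi","chi","chi"),
    chik = c(0L,1L,2L,2L),
    dihval = c(119.996,0.000,0.000,179.926),
    stringsAsFactors = FALSE
  ),
  ASP = data.frame(
    atom = c("CB","CG","OD1","OD2"),
    element = c("C","C","O","O"),
    dref = c("C","N","CA","CA"),
    aref = c("N","CA","CB","CB"),
    parent = c("CA","CB","CG","CG"),
    length = c(1.5301,1.5075,1.2080,1.3415),
    angle = c(109.480,109.463,119.959,119.999),
    dihtype = c("fixed","chi","chi","chi"),
    chik = c(0L,1L,2L,2L),
    dihval = c(120.011,0.000,0.000,179.936),
    stringsAsFactors = FALSE
  ),
  CYS = data.frame(
    atom = c("CB","SG"),
    element = c("C","S"),
    dref = c("C","N"),
    aref = c("N","CA"),
    parent = c("CA","CB"),
    length = c(1.5285,1.8141),
    angle = c(109.496,109.498),
    dihtype = c("fixed","chi"),
    chik = c(0L,1L),
    dihval = c(120.014,0.000),
    stringsAsFactors = FALSE
  ),
  GLN = data.frame(
    atom = c("CB","CG","CD","OE1","NE2"),
    element = c("C","C","C","O","N"),
    dref = c("C","N","CA","CB","CB"),
    aref = c("N","CA","CB","CG","CG"),
    parent = c("CA","CB","CG","CD","CD"),
    length = c(1.5288,1.5284,1.5066,1.2122,1.3471),
    angle = c(109.459,109.534,109.543,119.937,120.093),
    dihtype = c("fixed","chi","chi","chi","chi"),
    chik = c(0L,1L,2L,3L,3L),
    dihval = c(120.066,0.000,0.000,0.000,179.957),
    stringsAsFactors = FALSE
  ),
  GLU = data.frame(
    atom = c("CB","CG","CD","OE1","OE2"),
    element = c("C","C","C","O","O"),
    dref = c("C","N","CA","CB","CB"),
    aref = c("N","CA","CB","CG","CG"),
    parent = c("CA","CB","CG","CD","CD"),
    length = c(1.5302,1.5306,1.5076,1.2084,1.3425),
    angle = c(109.482,109.402,109.430,120.003,119.998),
    dihtype = c("fixed","chi","chi","chi","chi"),
    chik = c(0L,1L,2L,3L,3L),
    dihval = c(119.956,0.000,0.000,0.000,179.937),
    stringsAsFactors = FALSE
  ),
  GLY = data.frame(atom = character(0), element = character(0), dref = character(0), aref = character(0), parent = character(0), length = numeric(0), angle = numeric(0), dihtype = character(0), chik = integer(0), dihval = numeric(0), stringsAsFactors = FALSE),
  HIS = data.frame(
    atom = c("CB","CG","ND1","CD2","CE1","NE2"),
    element = c("C","C","N","C","C","N"),
    dref = c("C","N","CA","CA","CB","CG"),
    aref = c("N","CA","CB","CB","CG","ND1"),
    parent = c("CA","CB","CG","CG","ND1","CE1"),
    length = c(1.5337,1.5100,1.3513,1.3376,1.3369,1.3370),
    angle = c(111.125,112.979,120.329,129.928,107.862,107.617),
    dihtype = c("fixed","chi","chi","chi","fixed","fixed"),
    chik = c(0L,1L,2L,2L,0L,0L),
    dihval = c(122.779,0.000,0.000,-179.846,-179.905,0.043),
    stringsAsFactors = FALSE
  ),
  ILE = data.frame(
    atom = c("CB","CG1","CG2","CD1"),
    element = c("C","C","C","C"),
    dref = c("C","N","N","CA"),
    aref = c("N","CA","CA","CB"),
    parent = c("CA","CB","CB","CG1"),
    length = c(1.5288,1.5294,1.5303,1.5288),
    angle = c(109.430,109.547,109.458,109.547),
    dihtype = c("fixed","chi","chi","chi"),
    chik = c(0L,1L,1L,2L),
    dihval = c(120.073,0.000,119.972,0.000),
    stringsAsFactors = FALSE
  ),
  LEU = data.frame(
    atom = c("CB","CG","CD1","CD2"),
    element = c("C","C","C","C"),
    dref = c("C","N","CA","CA"),
    aref = c("N","CA","CB","CB"),
    parent = c("CA","CB","CG","CG"),
    length = c(1.5286,1.5303,1.5300,1.5285),
    angle = c(109.416,109.495,109.500,109.501),
    dihtype = c("fixed","chi","chi","chi"),
    chik = c(0L,1L,2L,2L),
    dihval = c(119.973,0.000,0.000,-120.092),
    stringsAsFactors = FALSE
  ),
  LYS = data.frame(
    atom = c("CB","CG","CD","CE","NZ"),
    element = c("C","C","C","C","N"),
    dref = c("C","N","CA","CB","CG"),
    aref = c("N","CA","CB","CG","CD"),
    parent = c("CA","CB","CG","CD","CE"),
    length = c(1.5300,1.5307,1.5308,1.5291,1.4694),
    angle = c(109.453,109.418,109.441,109.465,109.500),
    dihtype = c("fixed","chi","chi","chi","chi"),
    chik = c(0L,1L,2L,3L,4L),
    dihval = c(119.967,0.000,0.000,0.000,0.000),
    stringsAsFactors = FALSE
  ),
  MET = data.frame(
    atom = c("CB","CG","SD","CE"),
    element = c("C","C","S","C"),
    dref = c("C","N","CA","CB"),
    aref = c("N","CA","CB","CG"),
    parent = c("CA","CB","CG","SD"),
    length = c(1.5294,1.5284,1.8137,1.8135),
    angle = c(109.427,109.545,109.506,100.034),
    dihtype = c("fixed","chi","chi","chi"),
    chik = c(0L,1L,2L,3L),
    dihval = c(120.037,0.000,0.000,0.000),
    stringsAsFactors = FALSE
  ),
  PHE = data.frame(
    atom = c("CB","CG","CD1","CD2","CE1","CE2","CZ"),
    element = c("C","C","C","C","C","C","C"),
    dref = c("C","N","CA","CA","CB","CB","CG"),
    aref = c("N","CA","CB","CB","CG","CG","CD1"),
    parent = c("CA","CB","CG","CG","CD1","CD2","CE1"),
    length = c(1.5289,1.5052,1.3817,1.3832,1.3820,1.3819,1.3806),
    angle = c(109.474,109.517,120.058,120.005,120.029,119.977,120.047),
    dihtype = c("fixed","chi","chi","chi","fixed","fixed","fixed"),
    chik = c(0L,1L,2L,2L,0L,0L,0L),
    dihval = c(120.094,0.000,0.000,-179.757,-179.994,-179.839,0.048),
    stringsAsFactors = FALSE
  ),
  PRO = data.frame(
    atom = c("CB","CG","CD"),
    element = c("C","C","C"),
    dref = c("C","N","CA"),
    aref = c("N","CA","CB"),
    parent = c("CA","CB","CG"),
    length = c(1.5434,1.5426,1.5437),
    angle = c(104.722,105.059,105.063),
    dihtype = c("fixed","chi","chi"),
    chik = c(0L,1L,2L),
    dihval = c(118.841,0.000,0.000),
    stringsAsFactors = FALSE
  ),
  SER = data.frame(
    atom = c("CB","OG"),
    element = c("C","O"),
    dref = c("C","N"),
    aref = c("N","CA"),
    parent = c("CA","CB"),
    length = c(1.5287,1.4283),
    angle = c(109.471,109.512),
    dihtype = c("fixed","chi"),
    chik = c(0L,1L),
    dihval = c(120.020,0.000),
    stringsAsFactors = FALSE
  ),
  THR = data.frame(
    atom = c("CB","OG1","CG2"),
    element = c("C","O","C"),
    dref = c("C","N","N"),
    aref = c("N","CA","CA"),
    parent = c("CA","CB","CB"),
    length = c(1.5290,1.4280,1.5301),
    angle = c(109.411,109.505,109.525),
    dihtype = c("fixed","chi","chi"),
    chik = c(0L,1L,1L),
    dihval = c(120.000,0.000,120.031),
    stringsAsFactors = FALSE
  ),
  TRP = data.frame(
    atom = c("CB","CG","CD1","CD2","NE1","CE2","CE3","CZ2","CZ3","CH2"),
    element = c("C","C","C","C","N","C","C","C","C","C"),
    dref = c("C","N","CA","CA","CB","CB","CB","CG","CG","CD2"),
    aref = c("N","CA","CB","CB","CG","CG","CG","CD2","CD2","CE2"),
    parent = c("CA","CB","CG","CG","CD1","CD2","CD2","CE2","CE3","CZ2"),
    length = c(1.5286,1.5067,1.3426,1.4639,1.3686,1.4068,1.3961,1.3906,1.3659,1.3773),
    angle = c(109.523,109.442,126.496,126.512,109.932,106.076,134.047,119.346,119.795,119.806),
    dihtype = c("fixed","chi","chi","chi","fixed","fixed","fixed","fixed","fixed","fixed"),
    chik = c(0L,1L,2L,2L,0L,0L,0L,0L,0L,0L),
    dihval = c(120.026,0.000,0.000,-179.622,-179.944,-179.958,-0.784,179.825,-179.639,-0.221),
    stringsAsFactors = FALSE
  ),
  TYR = data.frame(
    atom = c("CB","CG","CD1","CD2","CE1","CE2","CZ","OH"),
    element = c("C","C","C","C","C","C","C","O"),
    dref = c("C","N","CA","CA","CB","CB","CG","CD1"),
    aref = c("N","CA","CB","CB","CG","CG","CD1","CE1"),
    parent = c("CA","CB","CG","CG","CD1","CD2","CE1","CZ"),
    length = c(1.5287,1.5062,1.3823,1.3830,1.3810,1.3809,1.3867,1.3582),
    angle = c(109.470,109.497,119.947,119.943,120.073,120.020,119.978,120.130),
    dihtype = c("fixed","chi","chi","chi","fixed","fixed","fixed","fixed"),
    chik = c(0L,1L,2L,2L,0L,0L,0L,0L),
    dihval = c(120.041,0.000,0.000,-179.692,179.976,-179.775,0.102,179.966),
    stringsAsFactors = FALSE
  ),
  VAL = data.frame(
    atom = c("CB","CG1","CG2"),
    element = c("C","C","C"),
    dref = c("C","N","N"),
    aref = c("N","CA","CA"),
    parent = c("CA","CB","CB"),
    length = c(1.5287,1.5299,1.5292),
    angle = c(109.445,109.509,109.490),
    dihtype = c("fixed","chi","chi"),
    chik = c(0L,1L,1L),
    dihval = c(120.004,0.000,-120.026),
    stringsAsFactors = FALSE
  )
)
.ringClosures <- list(
  HIS = list(c("CD2","NE2","1.3739")),
  PHE = list(c("CE2","CZ","1.3821")),
  TYR = list(c("CE2","CZ","1.3881")),
  TRP = list(c("NE1","CE2","1.3768"), c("CZ3","CH2","1.3877")),
  PRO = list(c("CD","N","1.4866"))
)
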