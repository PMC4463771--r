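# Independent atom-bookkeeping oracle: element masses typed from the
# standard atomic mass tables, formulas assembled from first principles.
# Deliberately shares no code with the package.

.OE <- c(C = 12.0, H = 1.00782503, N = 14.00307401, O = 15.99491462,
         P = 30.97376200)
.OELECTRON <- 0.00054858

oracleMass <- function(counts) {
  sum(counts * .OE[names(counts)])
}

# free fatty acid CnH(2n-2d)O2
oracleFaMass <- function(carbons, db) {
  oracleMass(c(C = carbons, H = 2 * carbons - 2 * db, O = 2))
}

# TAG = glycerol + 3 FA - 3 H2O
oracleTagMass <- function(chains) {
  glycerol <- oracleMass(c(C = 3, H = 8, O = 3))
  water <- oracleMass(c(H = 2, O = 1))
  glycerol + sum(vapply(chains, function(ch)
    oracleFaMass(ch[1], ch[2]), 0)) - 3 * water
}

oracleIonMz <- function(counts, charge) {
  (oracleMass(counts) - charge * .OELECTRON) / abs(charge)
}
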