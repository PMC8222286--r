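# Builds the packaged amino-acid descriptor table
# (inst/extdata/aa_descriptors_48_synthetic.csv).
#
# The method requires a table of real-valued physicochemical descriptors per
# residue partitioned into 16 hydrophobic, 17 steric and 15 electronic
# features (48 columns total), so that a 7-residue cleavage window encodes
# to 7 x 48 = 336 features and the hidden layer of the network is 336/3 =
# 112 units.
#
# The published descriptor sets of this shape are not redistributable here,
# so this table is a SYNTHETIC stand-in: a small number of well-established,
# accurately known property scales anchor each category, and the remaining
# columns are deterministic seeded linear combinations of those anchors plus
# residue-specific variation. The pipeline depends only on the table's shape
# and category semantics; users can substitute any conforming table at load
# time.
#
# Anchor scales (values as tabulated in standard references):
#   hydrophobic: Kyte-Doolittle hydropathy; Hopp-Woods hydrophilicity
#   steric:      average residue mass (Da); Zamyatnin residue volume (A^3);
#                maximal accessible surface area (A^2);
#                Charton polarizability
#   electronic:  net side-chain charge at pH 7; isoelectric point;
#                Grantham polarity

res <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

kd   <- c( 1.8, -4.5, -3.5, -3.5,  2.5, -3.5, -3.5, -0.4, -3.2,  4.5,
           3.8, -3.9,  1.9,  2.8, -1.6, -0.8, -0.7, -0.9, -1.3,  4.2)
hw   <- c(-0.5,  3.0,  0.2,  3.0, -1.0,  0.2,  3.0,  0.0, -0.5, -1.8,
          -1.8,  3.0, -1.3, -2.5,  0.0,  0.3, -0.4, -3.4, -2.3, -1.5)
mass <- c( 71.08, 156.19, 114.10, 115.09, 103.14, 128.13, 129.12, 57.05,
          137.14, 113.16, 113.16, 128.17, 131.19, 147.18,  97.12, 87.08,
          101.10, 186.21, 163.18,  99.13)
vol  <- c( 88.6, 173.4, 114.1, 111.1, 108.5, 143.8, 138.4,  60.1, 153.2,
          166.7, 166.7, 168.6, 162.9, 189.9, 112.7,  89.0, 116.1, 227.8,
          193.6, 140.0)
asa  <- c(129, 274, 195, 193, 167, 225, 223, 104, 224, 197,
          201, 236, 224, 240, 159, 155, 172, 285, 263, 174)
plz  <- c(0.046, 0.291, 0.134, 0.105, 0.128, 0.180, 0.151, 0.000, 0.230,
          0.186, 0.186, 0.219, 0.221, 0.290, 0.131, 0.062, 0.108, 0.409,
          0.298, 0.140)
chg  <- c(0, 1, 0, -1, 0, 0, -1, 0, 0.1, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0)
pi   <- c(6.00, 10.76, 5.41, 2.77, 5.07, 5.65, 3.22, 5.97, 7.59, 6.02,
          5.98,  9.74, 5.74, 5.48, 6.30, 5.68, 5.60, 5.89, 5.66, 5.96)
pol  <- c( 8.1, 10.5, 11.6, 13.0,  5.5, 10.5, 12.3,  9.0, 10.4,  5.2,
           4.9, 11.3,  5.7,  5.2,  8.0,  9.2,  8.6,  5.4,  6.2,  5.9)

z <- function(x) (x - mean(x)) / sd(x)

synth_cols <- function(anchors_z, from, n, prefix, seed_offset) {
  set.seed(46 + seed_offset)
  out <- matrix(NA_real_, nrow = 20, ncol = n)
  for (j in seq_len(n)) {
    w <- rnorm(ncol(anchors_z))
    v <- as.vector(anchors_z %*% w) + rnorm(20, sd = 0.6)
    out[, j] <- round(z(v), 3)
  }
  colnames(out) <- sprintf("%s%02d", prefix, from + seq_len(n) - 1)
  out
}

hyd <- cbind(hyd01 = kd, hyd02 = hw,
             synth_cols(cbind(z(kd), z(hw)), 3, 14, "hyd", 1))
ste <- cbind(ste01 = mass, ste02 = vol, ste03 = asa, ste04 = plz,
             synth_cols(cbind(z(mass), z(vol), z(asa), z(plz)),
                        5, 13, "ste", 2))
ele <- cbind(ele01 = chg, ele02 = pi, ele03 = pol,
             synth_cols(cbind(z(chg), z(pi), z(pol)), 4, 12, "ele", 3))

tab  <- cbind(hyd, ste, ele)
cats <- c(rep("hydrophobic", 16), rep("steric", 17), rep("electronic", 15))

stopifnot(ncol(tab) == 48, nrow(tab) == 20, !anyNA(tab), !anyDuplicated(tab),
          length(cats) == 48)

out <- "inst/extdata/aa_descriptors_48_synthetic.csv"
con <- file(out, "w")
writeLines(paste(c("residue", colnames(tab)), collapse = ","), con)
writeLines(paste(c("category", cats), collapse = ","), con)
for (i in seq_len(20)) {
  writeLines(paste(c(res[i], format(tab[i, ], trim = TRUE, scientific = FALSE)),
                   collapse = ","), con)
}
close(con)
cat("wrote", out, "\n")
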