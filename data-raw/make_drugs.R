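# Dev script: generate the versioned built-in drug table (toy reduced
# heavy-atom geometries) shipped at inst/extdata/drugs.json.
# Run from the repo root: Rscript data-raw/make_drugs.R

rad <- c(C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1, F = 1.5, CL = 1.8)

atom <- function(name, element, x, y, z, hydrophobic = FALSE, donor = FALSE,
                 acceptor = FALSE, aromatic = FALSE, fcharge = 0) {
  list(name = name, element = element, x = x, y = y, z = z,
       radius = unname(rad[toupper(element)]),
       hydrophobic = hydrophobic, donor = donor, acceptor = acceptor,
       aromatic = aromatic, metal = FALSE, charged = fcharge != 0,
       fcharge = fcharge)
}

# planar hexagon of aromatic carbons centred at (cx, cy, 0)
hex <- function(cx, cy, prefix, r = 1.4) {
  ang <- (0:5) * pi / 3
  lapply(1:6, function(i)
    atom(paste0(prefix, i), "C", cx + r * cos(ang[i]), cy + r * sin(ang[i]), 0,
         hydrophobic = TRUE, aromatic = TRUE))
}

drugs <- list()

## EPI / DOX: anthracycline-like; three fused aromatic rings, hydroxyls,
## and a protonated amino sugar (+1). Epimers -> same toy geometry, the
## sugar hydroxyl flipped in z.
anthracycline <- function(flip) {
  atoms <- c(hex(0, 0, "A"), hex(2.4, 0, "B"), hex(4.8, 0, "C"))
  atoms <- c(atoms, list(
    atom("O1", "O", -1.0, 1.8, 0, acceptor = TRUE, donor = TRUE),
    atom("O2", "O", 5.8, 1.8, 0, acceptor = TRUE),
    atom("O3", "O", 5.8, -1.8, 0, acceptor = TRUE, donor = TRUE),
    # amino sugar arm
    atom("C7", "C", 2.4, -2.2, 0.8, hydrophobic = TRUE),
    atom("O4", "O", 2.4, -3.4, flip * 1.6, acceptor = TRUE, donor = TRUE),
    atom("N1", "N", 3.6, -3.0, 1.6, donor = TRUE, fcharge = 1)
  ))
  atoms
}
drugs$EPI <- list(net_charge = 1, atoms = anthracycline(+1))
drugs$DOX <- list(net_charge = 1, atoms = anthracycline(-1))

## MTX: pteridine-like aromatic core with ring nitrogens, benzamide, and a
## glutamate tail carrying two carboxylates (-2).
mtx <- c(hex(0, 0, "A"), hex(2.4, 0, "B"))
mtx[[2]]$element <- "N"; mtx[[2]]$name <- "N1"; mtx[[2]]$acceptor <- TRUE
mtx[[4]]$element <- "N"; mtx[[4]]$name <- "N3"; mtx[[4]]$acceptor <- TRUE
mtx[[8]]$element <- "N"; mtx[[8]]$name <- "N5"; mtx[[8]]$acceptor <- TRUE
for (i in c(2, 4, 8)) { mtx[[i]]$radius <- unname(rad["N"]); mtx[[i]]$hydrophobic <- FALSE }
mtx <- c(mtx, list(
  atom("N10", "N", 4.4, 1.2, 0, donor = TRUE),
  atom("N11", "N", -1.2, -1.8, 0, donor = TRUE)
))
mtx <- c(mtx, hex(6.8, 1.2, "P"))
mtx <- c(mtx, list(
  atom("C20", "C", 8.8, 1.2, 0, hydrophobic = TRUE),
  atom("O20", "O", 9.4, 2.3, 0, acceptor = TRUE),
  atom("N21", "N", 9.4, 0.0, 0, donor = TRUE),
  atom("C22", "C", 10.8, 0.0, 0.4, hydrophobic = TRUE),
  atom("O23", "O", 11.5, 1.2, 0.8, acceptor = TRUE, fcharge = -1),
  atom("C24", "C", 11.5, -1.3, 0.2, hydrophobic = TRUE),
  atom("O25", "O", 12.8, -1.3, 0.6, acceptor = TRUE, fcharge = -1)
))
drugs$MTX <- list(net_charge = -2, atoms = mtx)

## MIT: quinone-like ring plus aziridine and carbamate polar atoms (neutral).
mit <- hex(0, 0, "A")
mit <- c(mit, list(
  atom("O1", "O", -1.1, 1.9, 0, acceptor = TRUE),
  atom("O2", "O", 2.5, -1.1, 0, acceptor = TRUE),
  atom("N1", "N", 2.6, 1.2, 0.5, donor = TRUE),
  atom("N2", "N", -1.5, -1.6, 0.5, donor = TRUE),
  atom("C7", "C", 3.8, 0.4, 0.9, hydrophobic = TRUE),
  atom("O3", "O", 4.6, 1.4, 1.1, acceptor = TRUE, donor = TRUE)
))
drugs$MIT <- list(net_charge = 0, atoms = mit)

## 5FU: single pyrimidinedione ring with fluorine (neutral).
fu <- hex(0, 0, "A")
fu[[1]]$element <- "N"; fu[[1]]$name <- "N1"; fu[[1]]$donor <- TRUE
fu[[3]]$element <- "N"; fu[[3]]$name <- "N3"; fu[[3]]$donor <- TRUE
for (i in c(1, 3)) { fu[[i]]$radius <- unname(rad["N"]); fu[[i]]$hydrophobic <- FALSE }
fu <- c(fu, list(
  atom("O2", "O", 2.1, 2.1, 0, acceptor = TRUE),
  atom("O4", "O", -2.1, 2.1, 0, acceptor = TRUE),
  atom("F5", "F", 0.0, -2.8, 0, hydrophobic = TRUE)
))
drugs$`5FU` <- list(net_charge = 0, atoms = fu)

## CPT: four fused aromatic rings plus lactone oxygens and hydroxyl (neutral).
cpt <- c(hex(0, 0, "A"), hex(2.4, 0, "B"), hex(4.8, 0, "C"), hex(7.2, 0, "D"))
cpt[[8]]$element <- "N"; cpt[[8]]$name <- "N1"; cpt[[8]]$acceptor <- TRUE
cpt[[8]]$radius <- unname(rad["N"]); cpt[[8]]$hydrophobic <- FALSE
cpt <- c(cpt, list(
  atom("O1", "O", 8.6, 1.6, 0, acceptor = TRUE),
  atom("O2", "O", 8.6, -1.6, 0, acceptor = TRUE),
  atom("O3", "O", 7.2, -2.6, 0.6, acceptor = TRUE, donor = TRUE),
  atom("C25", "C", 9.6, 0.0, 0.4, hydrophobic = TRUE)
))
drugs$CPT <- list(net_charge = 0, atoms = cpt)

## CP: small non-aromatic oxazaphosphinane with phosphorus and two
## chloroethyl arms (neutral).
cp <- list(
  atom("P1", "P", 0.0, 0.0, 0.0),
  atom("O1", "O", 0.0, 1.5, 0.3, acceptor = TRUE),
  atom("O2", "O", 1.3, -0.8, 0.2, acceptor = TRUE),
  atom("N1", "N", -1.4, -0.8, 0.2, donor = TRUE),
  atom("C1", "C", 2.6, -0.2, 0.4, hydrophobic = TRUE),
  atom("C2", "C", 3.0, 1.2, 0.2, hydrophobic = TRUE),
  atom("C3", "C", -2.7, -0.2, 0.4, hydrophobic = TRUE),
  atom("N2", "N", -1.4, -2.2, 0.0, donor = TRUE),
  atom("C4", "C", -2.6, -3.0, 0.3, hydrophobic = TRUE),
  atom("CL1", "CL", -4.1, -2.3, 0.1, hydrophobic = TRUE),
  atom("C5", "C", -0.3, -3.1, -0.3, hydrophobic = TRUE),
  atom("CL2", "CL", -0.5, -4.8, 0.0, hydrophobic = TRUE)
)
drugs$CP <- list(net_charge = 0, atoms = cp)

## OrangeG: naphthalene disulfonate azo dye; the pose-template molecule the
## designed drugs are superposed onto (-2).
og <- c(hex(0, 0, "A"), hex(2.4, 0, "B"))
og <- c(og, list(
  atom("N1", "N", -1.6, 1.6, 0, aromatic = TRUE, acceptor = TRUE),
  atom("N2", "N", -2.8, 1.0, 0, aromatic = TRUE, acceptor = TRUE),
  atom("S1", "S", 4.2, 1.8, 0),
  atom("O1", "O", 5.2, 1.0, 0.6, acceptor = TRUE, fcharge = -1),
  atom("O2", "O", 4.4, 3.2, 0.2, acceptor = TRUE),
  atom("S2", "S", 4.2, -1.8, 0),
  atom("O3", "O", 5.2, -1.0, -0.6, acceptor = TRUE, fcharge = -1),
  atom("O4", "O", 4.4, -3.2, -0.2, acceptor = TRUE)
))
drugs$OrangeG <- list(net_charge = -2, atoms = og)

## toy: four-carbon tetrahedron, neutral; used by tests.
s <- 1.0
drugs$toy <- list(net_charge = 0, atoms = list(
  atom("C1", "C",  s,  s,  s, hydrophobic = TRUE),
  atom("C2", "C",  s, -s, -s, hydrophobic = TRUE),
  atom("C3", "C", -s,  s, -s, hydrophobic = TRUE),
  atom("C4", "C", -s, -s,  s, hydrophobic = TRUE)
))

# reference pose: centroid origin, axes = principal axes of the coordinates
# (right-handed), used for drug superposition onto the Orange G template.
for (nm in names(drugs)) {
  xyz <- t(vapply(drugs[[nm]]$atoms, function(a) c(a$x, a$y, a$z), numeric(3)))
  ctr <- colMeans(xyz)
  cc <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors
  if (det(ev) < 0) ev[, 3] <- -ev[, 3]
  drugs[[nm]]$reference_pose <- list(origin = as.numeric(ctr),
                                     axes = lapply(1:3, function(i) as.numeric(ev[, i])))
}

out <- list(version = "1.0",
            note = "synthetic toy reduced heavy-atom geometries; net charges are the assignment consistent with the designed component ratios",
            drugs = drugs)
jsonlite::write_json(out, "inst/extdata/drugs.json", auto_unbox = TRUE,
                     pretty = FALSE, digits = 10)
cat("wrote inst/extdata/drugs.json with", length(drugs), "drugs\n")
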