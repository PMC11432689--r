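# Coarse heavy-atom molecular templates used by the synthetic generator.
# Geometry is schematic (a jittered lattice slab, not physical MD): every
# downstream metric depends only on z-ordering, contact distances and ring
# planarity, all of which these templates control exactly.

# Serotonin-like ligand: fused 6- and 5-membered planar rings sharing two
# atoms (indole), a phenolic OH and an ethylamine tail. 13 heavy atoms,
# rings parallel to the xy plane in the local frame.
ligand_template <- function() {
  coords <- rbind(
    c( 1.212,  0.700, 0.0),  # C1 (shared)
    c( 0.000,  1.400, 0.0),  # C2
    c(-1.212,  0.700, 0.0),  # C3 (bears OH)
    c(-1.212, -0.700, 0.0),  # C4
    c( 0.000, -1.400, 0.0),  # C5
    c( 1.212, -0.700, 0.0),  # C6 (shared)
    c( 2.550,  1.130, 0.0),  # C7
    c( 3.380,  0.000, 0.0),  # C8
    c( 2.550, -1.130, 0.0),  # N9 (indole NH)
    c(-2.380,  1.380, 0.0),  # O10 (phenolic OH)
    c( 4.300,  0.900, 0.0),  # C11
    c( 5.300,  1.900, 0.3),  # C12
    c( 6.600,  1.400, 0.5)   # N13 (primary amine)
  )
  elements <- c(rep("C", 6), "C", "C", "N", "O", "C", "C", "N")
  masses <- c(C = 12.011, N = 14.007, O = 15.999)[elements]
  list(coords = coords, elements = elements, masses = unname(masses),
       rings = list(six = 1:6, five = c(1L, 7L, 8L, 9L, 6L)),
       donors = c(9L, 10L, 13L), acceptors = c(10L,13L))
}

# Phosphatidylcholine stand-in: choline N above the phosphate plane (z = 0
# local), phosphate at the plane, glycerol O and two tail carbons below.
popc_template <- function() {
  list(coords = rbind(c(0, 0, 1.0), c(0, 0, 0), c(0.5, 0.5, -2),
                      c(0, 0, -6), c(0.5, 0, -10)),
       elements = c("N", "P", "O", "C", "C"),
       masses = c(14.007, 30.974, 15.999, 12.011, 12.011),
       donors = integer(), acceptors = 3L)
}

# Cholesterol stand-in: 3-beta OH sitting slightly below the phosphate
# plane, ring/tail carbons deeper.
chol_template <- function() {
  list(coords = rbind(c(0, 0, -2.5), c(0.3, 0, -5), c(0, 0.3, -8),
                      c(0, 0, -11)),
       elements = c("O", "C", "C", "C"),
       masses = c(15.999, 12.011, 12.011, 12.011),
       donors = 1L, acceptors = 1L)
}

# Ganglioside stand-in: ceramide anchor plus a sugar column whose top
# oxygen reaches `headgroup_rise` Angstrom above the phospholipid maximum
# (choline) height of +1 local.
ganglioside_template <- function(headgroup_rise) {
  top <- 1 + headgroup_rise
  list(coords = rbind(c(0, 0, -3), c(0, 0, 0), c(0.2, 0, top / 3),
                      c(0, 0.2, 2 * top / 3), c(0, 0, top)),
       elements = c("C", "C", "O", "C", "O"),
       masses = c(12.011, 12.011, 15.999, 12.011, 15.999),
       donors = integer(), acceptors = c(3L, 5L))
}

# Headgroup rise above the phospholipid maximum, per ganglioside kind.
# GM1/GM3 carry one sialic acid with four/two sugars, GT1b three sialic
# acids; heights are chosen only to make the geometries distinguishable.
ganglioside_rise <- c("GM1-like" = 12, "GM3-like" = 8, "GT1b-like" = 16)
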