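# small hand-built models reused across tests

# two-stage model: juveniles mature with prob 0.5, adults persist at 0.8,
# adults produce 1 sexual recruit per year
fix_two_stage <- function(f = 1, cvals = 0) {
  Fm <- matrix(c(0, 0, f, 0), 2, 2)
  Cm <- matrix(c(0, 0, cvals, 0), 2, 2)
  mpm(U = matrix(c(0, 0.5, 0, 0.8), 2, 2), F = Fm, C = Cm,
      species_id = "two_stage")
}

# single-stage model with survival p and fertility f
fix_single <- function(p = 0.8, f = 0.5) {
  mpm(U = matrix(p), F = matrix(f), species_id = "single")
}

# 3-stage progressive model passing all selection criteria
fix_three_stage <- function(meta = species_meta()) {
  U <- matrix(c(0.1, 0.4, 0,
                0, 0.2, 0.5,
                0, 0.1, 0.6), 3, 3)
  Fm <- matrix(0, 3, 3)
  Fm[1, 3] <- 2
  mpm(U, Fm, species_id = "three_stage", meta = meta)
}

# 3-stage semelparous Leslie chain: reproduction only from stage 3
fix_leslie3 <- function(s1 = 0.5, s2 = 0.4, f = 10) {
  U <- matrix(0, 3, 3)
  U[2, 1] <- s1
  U[3, 2] <- s2
  Fm <- matrix(0, 3, 3)
  Fm[1, 3] <- f
  mpm(U, Fm, species_id = "leslie3")
}
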