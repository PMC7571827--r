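# Counter-based uniform random numbers.
#
# Every variate used by the simulation is a pure function of
# (seed, person_id, slot): any person's draws can be reproduced in isolation,
# independently of cohort size or iteration order, and the screened and
# unscreened arms of a paired run automatically share common random numbers.
# The mixing function is the 32-bit murmur3 finalizer applied twice, carried
# out in doubles (exact up to 2^53) because R has no unsigned 32-bit type.

.M32 <- 4294967296

# (a * b) mod 2^32 for doubles a, b in [0, 2^32)
.mul32 <- function(a, b) {
  ah <- a %/% 65536
  al <- a - ah * 65536
  (((ah * b) %% 65536) * 65536 + al * b) %% .M32
}

.xor32 <- function(a, b) {
  ah <- as.integer(a %/% 65536)
  al <- as.integer(a %% 65536)
  bh <- as.integer(b %/% 65536)
  bl <- as.integer(b %% 65536)
  as.numeric(bitwXor(ah, bh)) * 65536 + as.numeric(bitwXor(al, bl))
}

# murmur3 fmix32 avalanche finalizer
.fmix32 <- function(h) {
  h <- .xor32(h, h %/% 65536)
  h <- .mul32(h, 2246822507)   # 0x85ebca6b
  h <- .xor32(h, h %/% 8192)
  h <- .mul32(h, 3266489909)   # 0xc2b2ae35
  .xor32(h, h %/% 65536)
}

#' Counter-based uniform draws
#'
#' Deterministic uniform variates in (0, 1), each a pure function of
#' `(seed, person, slot)`. Used for every stochastic draw in the simulation;
#' the `slot` argument indexes the purpose of the draw (see `.SLOT`).
#'
#' @param seed integer master seed.
#' @param person integer person identifier(s).
#' @param slot integer draw-purpose slot(s); recycled against `person`.
#' @return numeric vector of uniforms in (0, 1).
#' @keywords internal
runif_ctr <- function(seed, person, slot) {
  h <- (seed %% .M32 + .mul32(person %% .M32, 2654435761)) %% .M32
  h <- .fmix32(h)
  h <- .fmix32(.xor32(h, .mul32(slot %% .M32, 2246822519)))
  (h + 0.5) / .M32
}

# Draw-purpose slot map. Screening slots are offset by the age index
# j = age - 50 (j in 0..29 leaves headroom beyond the 50-69 grid).
.SLOT <- list(
  ocd_year    = 1,   # other-cause death: year of death
  ocd_frac    = 2,   # other-cause death: uniform placement within the year
  onset       = 3,   # exponential deviate for onset age
  onset_state = 4,   # categorical draw for the state at onset
  prog_hold   = 10,  # + 2k: holding time in the k-th visited state
  prog_dest   = 11,  # + 2k: event type / destination at exit of k-th state
  treat       = 60,  # treatment allocation at diagnosis (shared across arms)
  surv        = 61,  # baseline survival deviate at clinical diagnosis
  as_switch   = 62,  # active-surveillance switch time
  cure        = 63,  # cure draw for screen-detected relevant cancers
  never_att   = 64,  # person-level attender draw ("never_attender" mode)
  att         = 70,  # + j: attendance at the test offered at age 50 + j
  pos         = 110, # + j: test positivity given preclinical state
  cmp         = 150, # + j: biopsy compliance
  sens        = 190  # + j: biopsy sensitivity
)
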