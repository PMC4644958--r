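# Physical constants used throughout. Energies in kcal/mol, lengths in
# Angstrom, masses in amu, temperatures in K unless stated otherwise.

# Coulomb conversion constant, kcal*A/(mol*e^2)
K_COULOMB <- 332.0637

# Boltzmann constant, kcal/(mol*K)
KB_KCAL <- 1.9872041e-3

# Gas constant equals KB_KCAL on the molar scale used here
R_KCAL <- KB_KCAL

# Intrinsic Born radius offset (A) of the pairwise-descreening GB model
GB_OFFSET <- 0.09

# SI constants for thermochemistry
.const <- list(
  h      = 6.62607015e-34,   # J s
  kB     = 1.380649e-23,     # J/K
  N_A    = 6.02214076e23,    # 1/mol
  c_cm   = 2.99792458e10,    # cm/s
  amu    = 1.66053906892e-27,# kg
  P0     = 101325            # Pa (1 atm)
)

# Conversion: sqrt(kcal/mol/A^2/amu) -> wavenumber (cm^-1).
# lambda[SI, s^-2] = lambda * (4184/N_A) / (1e-20 * amu); nu~ = sqrt(lambda)/(2 pi c)
FREQ_CM1 <- sqrt((4184 / .const$N_A) / (1e-20 * .const$amu)) / (2 * pi * .const$c_cm)
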