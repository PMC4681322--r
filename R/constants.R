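# CODATA 2018 values; SI units unless noted.
.const <- list(
  e        = 1.602176634e-19,   # elementary charge, C
  eps0     = 8.8541878128e-12,  # vacuum permittivity, F/m
  kB       = 1.380649e-23,      # Boltzmann constant, J/K
  NA_      = 6.02214076e23,     # Avogadro number, 1/mol
  m_per_A  = 1e-10,             # metres per Angstrom
  A3_per_L = 1e27               # cubic Angstroms per litre
)

# Standard atomic weights (IUPAC 2021), g/mol.
.atomic_mass <- c(C = 12.011, H = 1.008, O = 15.999, Na = 22.98977)
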