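# Shared physical constants (SI)

# Permeability of free space, T m / A
MU0 <- 4 * pi * 1e-7
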