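# shared objects for the suite; everything is generated in code
tgt10 <- tubule_indices(10, 0)
tgt6 <- tubule_indices(6, 0)
p10 <- energy_params(E_B = 6, B = 20, target = tgt10)
p6 <- energy_params(E_B = 6, B = 20, target = tgt6)
flat_params <- function(E_B = 4, B = 20)
  energy_params(E_B = E_B, B = B, theta0 = c(pi, pi, pi))

# internal helpers exercised by the suite
cross3 <- tubulemc:::cross3
single_monomer <- tubulemc:::single_monomer
removable_monomers <- tubulemc:::removable_monomers
attempt_fusion_r <- tubulemc:::attempt_fusion_r
attempt_fission_r <- tubulemc:::attempt_fission_r
.sample_fixed_topology_cpp <- tubulemc:::.sample_fixed_topology_cpp
.sheet_energy_cpp <- tubulemc:::.sheet_energy_cpp
bennett_bar <- tubulemc:::bennett_bar
gauss_legendre_01 <- tubulemc:::gauss_legendre_01
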