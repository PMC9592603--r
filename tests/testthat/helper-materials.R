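# Shared fixtures built in code.
generic_cell <- function() surface_chemistry("cell", 39, 2.6, 71, psi0 = -40)
phys_medium <- function() medium_spec()

# Independent second coding of the van Oss contact rules, used as the oracle
# for the implementations in R/materials.R.  Works on raw components.
oracle_contact_lw <- function(g1, g2, g3) {
  2 * (sqrt(g3) - sqrt(g1)) * (sqrt(g2) - sqrt(g3))
}
oracle_contact_ab <- function(p1, n1, p2, n2, p3, n3) {
  2 * (sqrt(p3) * (sqrt(n1) + sqrt(n2) - sqrt(n3)) +
         sqrt(n3) * (sqrt(p1) + sqrt(p2) - sqrt(p3)) -
         sqrt(p1 * n2) - sqrt(n1 * p2))
}

random_chemistry <- function(name = "rand") {
  surface_chemistry(name,
                    gamma_lw = runif(1, 0, 60),
                    gamma_plus = runif(1, 0, 30),
                    gamma_minus = runif(1, 0, 80),
                    psi0 = runif(1, -60, 20))
}
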