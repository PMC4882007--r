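# Energy-balance model parameters for diet-induced-obese Sprague-Dawley rats.
# Flat key = value format; read with read_params_config().
#
# Literature placeholders: energy densities and deposition costs are rodent
# literature values assumed species-invariant; the diet-induced thermogenesis
# fraction comes from rat growth analyses; the mass-specific metabolic rates
# are mouse values carried to a 350 g lean rat by Kleiber scaling (see
# kleiber_translate()). Override any entry from a study-specific source when
# available.

rho_fm = 9.4       # kcal/g, energy density of fat mass
rho_ffm = 1.8      # kcal/g, energy density of fat-free mass
eta_fm = 0.18      # kcal/g, fat deposition cost
eta_ffm = 0.23     # kcal/g, fat-free deposition cost
beta = 0.24        # dimensionless, diet-induced thermogenesis fraction
gamma_fm = 0.01    # kcal/g/day, fat-mass specific metabolic rate
gamma_ffm = 0.1    # kcal/g/day, fat-free-mass specific metabolic rate
lam = 0.087        # kcal/g/day, physical-activity coefficient (fitted)
K = 0              # kcal/day, basal thermogenesis offset (fitted; 0 for CR)
alpha = 0.92       # g/g, constant energy-partition slope (TLS estimate)
I0 = 100           # kcal/day, baseline food intake (study-specific)

# Hill drug effect on energy expenditure (CB1-antagonist study)
drug_d0 = 13       # kcal/day, handling stress (all dosed arms)
drug_dmax = 37     # kcal/day, maximal drug effect
drug_ed50 = 10     # mg/kg, half-maximal dose
drug_t_start = 0   # day, treatment window start
drug_t_end = 23    # day, treatment window end (exclusive)
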