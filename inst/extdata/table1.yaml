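# Literature parameter table of the cortisol transport model.
# Pressures in mmHg; all other quantities SI.
P_c: 30            # capillary hydrostatic pressure [mmHg]
L_pc: 6.5e-10      # capillary hydraulic conductivity [m s^-1 mmHg^-1]
k_DE: 1.01e-3      # dermal clearance constant of steroids [s^-1]
D_sg_wall: 2.84e-10  # cortisol diffusion, sweat-gland wall [m^2 s^-1]
D_ISF: 2.84e-10    # cortisol diffusion, ISF [m^2 s^-1]
D_sg: 2.84e-10     # cortisol diffusion, sweat [m^2 s^-1]
A_sg: 1.96e-11     # effective area of sweat gland [m^2]
A_c: 1.5e-8        # effective capillary surface area [m^2]
A_ISF: 2.2e-8      # effective ISF cross-sectional area [m^2]
V_p: 3.02e-13      # effective capillary volume [m^3]
V_ISF: 6.0e-13     # effective ISF volume [m^3]
P_ISF: -3          # interstitial hydrostatic pressure [mmHg]
alpha: 0.05        # free-cortisol fraction of total blood cortisol
K_wc: 20           # water-to-cortisol volumetric flow-rate ratio
h_sg: 5.0e-5       # sweat-gland wall thickness [m]
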