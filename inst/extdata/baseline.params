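# trophos baseline cell-model parameters
# units: concentrations mM, time s, length um, mass Da, areas um^2
#
# Transport kinetics: measured reference values for the E. coli glucose
# PTS and maltose ABC systems (K_T = K_Tp ~ 10 uM, K_D = 1 uM), with the
# ABC association and dissociation steps 100-fold slower than their PTS
# counterparts to reflect the slow diffusion of the bulky binding protein.
k1  = 20000     # PTS substrate-transporter association, /mM/s (K_T = k2/k1 = 0.01 mM)
k2  = 200       # PTS translocation, /s
k0f = 100000    # substrate-BP association, /mM/s
k0r = 100       # substrate-BP dissociation, /s (K_D = 0.001 mM)
k1p = 200       # loaded-BP docking on transport unit, /mM/s (= 0.01 k1)
k2p = 200       # ABC translocation, /s (= k2)
k3p = 2         # BP release from transport unit, /s (= 0.01 k2p; K_Tp = 0.009901 mM)
#
# Cell model: package baseline estimates at E. coli scale (see the
# methods vignette for the justification of each choice).
D = 100             # substrate diffusivity, um^2/s
kE = 2              # catabolic turnover per lumped metabolic unit, /s
K_ME = 0.1          # catabolic half-saturation, mM
kW = 0.5            # membrane-unit synthesis per enzyme, /s (FAS-scale)
K_MW = 0.1          # membrane-synthesis half-saturation, mM
kR = 20             # ribosome elongation, aa/s
K_MR = 0.1          # protein-synthesis half-saturation, mM
n_BP = 375          # aa per binding protein (4-fold cheaper than a transport unit)
n_T = 1500          # aa per transport unit
n_E = 2500          # aa per lumped metabolic unit
n_M = 500           # aa per membrane-synthesis enzyme
n_R = 7459          # aa per ribosome (protein part)
a_w = 5e-7          # membrane area per membrane unit, um^2 (0.5 nm^2)
a_T = 2.5e-5        # inner-membrane footprint per transport unit, um^2 (25 nm^2)
f_SA = 0.3          # inner-membrane fraction available to transport units
rho_cyto = 3e5      # cytoplasmic density cap, mM*Da (~300 g/L)
rho_peri = 5e4      # periplasmic density cap, mM*Da (~50 g/L)
m_S = 180           # substrate mass, Da (hexose)
m_A = 110           # free amino-acid precursor mass, Da
m_aa = 110          # mass per protein-incorporated aa, Da
m_W = 700           # membrane unit (lipid) mass, Da
phi_O_cyto = 0.35   # fixed "other" cytoplasmic proteome fraction
phi_O_peri = 0.05   # fixed "other" periplasmic proteome fraction
r_min = 0.06        # minimum radius, um (SA:V <= 50 /um)
r_max = 10          # model domain bound on radius, um
S_ext = 0.001       # default external substrate, mM
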