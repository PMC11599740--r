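# Observation set used to identify logical parameters of the HIF-1 model.
# Formula 1: the pathogenic pattern (high VEGF/OGT/GLUT-1/HIF-1/p53, low AKT)
# can settle permanently once entered.
((VEGF = 1 & OGT = 1 & GLUT1 = 1 & HIF-1 = 1 & AKT = 0 & P53 = 1) -> EF(AG(VEGF = 1 & OGT = 1 & GLUT1 = 1 & HIF-1 = 1 & AKT = 0 & P53 = 1)))
# Formula 2: the homeostatic pattern (everything off, AKT on) can settle
# permanently once entered.
((VEGF = 0 & OGT = 0 & GLUT1 = 0 & HIF-1 = 0 & AKT = 1 & P53 = 0) -> EF(AG(VEGF = 0 & OGT = 0 & GLUT1 = 0 & HIF-1 = 0 & AKT = 1 & P53 = 0)))
# Formula 3: with VEGF and HIF-1 suppressed but GLUT-1, AKT and p53 active,
# the fully engaged intermediate configuration is reachable after one step.
((VEGF = 0 & HIF-1 = 0 & GLUT1 = 1 & AKT = 1 & P53 = 1) -> EX(EF(VEGF = 0 & GLUT1 = 1 & ERK = 1 & OGT = 1 & CMYC = 1 & BCAT = 1 & HIF-1 = 0 & AKT = 1 & P53 = 1)))
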