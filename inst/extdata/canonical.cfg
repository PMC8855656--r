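# model parameters (units: mV, s, nS, pA, nF, mM)
C = 0.001
gNaF = 105
gNaP = 4.9699999999999998
gKDR = 79
gKA = 1.1299999999999999
gh = 0.34000000000000002
gCaS = 3.2999999999999998
gL = 1.8799999999999999
gSyn = 1.02
ECa = 160
ELRef = -55
ENaRef = 65
ESyn = -70
IPumpMax = 40.259999999999998
Nae = 120
Ke = 9
Ki = 130
M = 0
alpha = 4.6822553381552918
tau_h_scale = 1
RTF = 26.449999999999999
# kinetics constants
kinetics.mh_k1 = 2.2599999999999998
kinetics.mh_k2 = 6.1500000000000004
kinetics.mh_vhalf = -52.100000000000001
kinetics.tauh_base = 0.5
kinetics.tauh_amp = 1
kinetics.tauh_slope = 0.10000000000000001
kinetics.tauh_vhalf = -53.229999999999997
kinetics.hNaF_slope = 7
kinetics.hNaF_vhalf = -26
kinetics.thNaF_s1 = 15
kinetics.thNaF_s2 = -16
kinetics.thKDR_s1 = 40
kinetics.thKDR_s2 = -50
kinetics.tCaS_scale = 1
kinetics.tCaS_mode = 0
# protocol
protocol.transient = 5000
protocol.record = 2000
protocol.sample_dt = 0.00050000000000000001
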