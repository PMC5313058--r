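# Electrical and geometrical parameters: rat optic nerve axon preset.
# Conductances mS/cm^2, capacitances uF/cm^2, resistivities ohm.cm,
# potentials mV, lengths/diameters um, periaxonal widths nm,
# spiral_area nm^2, periodicity nm.
name: optic_nerve
g_Na: 3000
g_Ks: 80
g_Nap: 5
g_L_node: 80
g_L_internode: 0.1
g_my: 1.0
c_ax: 0.9
c_my: 0.9
rho_ax: 70
rho_p: 70
E_r: -82
E_Lk: -83.38
E_Na: 50
E_K: -84
d_node: 0.73
L_node: 1.02
L_paranode: 2.11
w_paranode: 0.0077
d_axon_internode: 0.82
w_internode: 15
g_ratio: 0.78
N_wraps: 7
L_internode: 139.26
spiral_area: 170
periodicity: 15.6
internodal_compartments: 66
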