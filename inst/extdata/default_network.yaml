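neurons:
  A:
    Cm: 50.0
    gL: 2.5
    gCaT: 0.1
    gSK: 0.5
    gH: 1.0
  B:
    Cm: 50.0
    gL: 2.5
    gCaT: 0.1
    gSK: 0.5
    gH: 1.0
  E1:
    Cm: 50.0
    gL: 2.5
    gCaT: 0.1
    gSK: 0.5
    gH: 1.0
  CSN:
    gCaT: 0.4
    gH: 6.0
    gSK: 10.0
    gCaL: 1.5
    Ca_ex: 50.0
    eps: 0.01
    ks: 2.0
    theta_aT: -60.0
    sigma_aT: -4.5
    theta_rT: -78.0
    sigma_rT: 4.0
    tau_r0: 50.0
    tau_r1: 30.0
    theta_rrT: -70.0
    sigma_rrT: -5.0
    theta_rf: -95.0
    sigma_rf: 8.0
    prf: 0.8
    theta_rs: -95.0
  E2:
    Cm: 50.0
    gCaT: 4.0
    gH: 10.0
    gSK: 3.0
    ks: 2.0
    theta_aT: -67.0
    theta_rf: -90.0
    theta_rs: -90.0
    tau_r0: 20.0
    tau_r1: 30.0
    theta_rrT: -70.0
    sigma_rrT: -5.0
    kCa: 0.013
    eps: 0.015
  E3:
    Cm: 50.0
    gCaT: 4.0
    gH: 10.0
    gSK: 3.0
    ks: 2.0
    theta_aT: -67.0
    theta_rf: -90.0
    theta_rs: -90.0
    tau_r0: 20.0
    tau_r1: 30.0
    theta_rrT: -70.0
    sigma_rrT: -5.0
    kCa: 0.013
    eps: 0.015
  I1: []
  I2: []
  I_A1: []
  I_A2: []
  I_A3: []
  I_B: []
synapses:
  A->E1: 20.0
  E1->I1: 25.0
  I1->E2: 25.0
  E2->I2: 25.0
  I2->E3: 25.0
  E3->I1: 15.0
  E1->I_A1: 25.0
  E2->I_A2: 25.0
  E3->I_A3: 25.0
  I_A1->CSN: 20.0
  I_A2->CSN: 20.0
  I_A3->CSN: 20.0
  B->CSN: 3.2
  B->I_B: 25.0
  I_B->I1: 25.0
  I_B->I2: 25.0
  I_B->I_A2: 25.0
  I_B->I_A3: 25.0
motifs:
  dual_excitatory:
    a_inhibitory: no
    b_inhibitory: no
    a_params:
      Cm: 50.0
      gL: 2.5
      gCaT: 0.1
      gSK: 0.5
      gH: 1.0
    b_params:
      Cm: 50.0
      gL: 2.5
      gCaT: 0.1
      gSK: 0.5
      gH: 1.0
    csn_params:
      gCaT: 0.1
      gH: 2.0
      gSK: 2.0
      gL: 2.0
    gA_CSN: 2.0
    gB_CSN: 2.0
  dual_inhibitory:
    a_inhibitory: yes
    b_inhibitory: yes
    a_params: []
    b_params: []
    csn_params:
      Cm: 50.0
      gCaT: 4.0
      gH: 10.0
      gSK: 3.0
      ks: 2.0
      theta_aT: -67.0
      theta_rf: -90.0
      theta_rs: -90.0
      tau_r0: 20.0
      tau_r1: 30.0
      theta_rrT: -70.0
      sigma_rrT: -5.0
      kCa: 0.013
      eps: 0.015
    gA_CSN: 20.0
    gB_CSN: 20.0
  inhibitory_excitatory:
    a_inhibitory: yes
    b_inhibitory: no
    a_params: []
    b_params:
      Cm: 50.0
      gL: 2.5
      gCaT: 0.1
      gSK: 0.5
      gH: 1.0
    csn_params:
      gCaT: 0.4
      gH: 6.0
      gSK: 8.0
      gCaL: 1.5
      Ca_ex: 60.0
      eps: 0.01
      ks: 2.0
      theta_aT: -60.0
      sigma_aT: -4.5
      theta_rT: -78.0
      sigma_rT: 4.0
      tau_r0: 25.0
      tau_r1: 30.0
      theta_rrT: -70.0
      sigma_rrT: -5.0
      theta_rf: -95.0
      sigma_rf: 8.0
      prf: 0.8
      theta_rs: -95.0
    gA_CSN: 20.0
    gB_CSN: 3.6
stimulus:
  duration: 50.0
  amplitude: 200.0
solver:
  method: lsoda
  rtol: 1.0e-06
  atol: 1.0e-08
  dt_out: 0.01
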