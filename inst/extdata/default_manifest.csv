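sample_id,m_X_g,m_Exsolv_g,m_Extr_g,nominal_tcmp
S1,1,15,0.25,10.7
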