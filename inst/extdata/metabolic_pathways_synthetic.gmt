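pathway1	synthetic metabolic pathway (names match the timepoints preset)	pw1-01	pw1-02	pw1-03	pw1-04	pw1-05	pw1-06	pw1-07	pw1-08	pw1-09	pw1-10	pw1-11	pw1-12	pw1-13	pw1-14	pw1-15	pw1-16
pathway2	synthetic metabolic pathway (names match the timepoints preset)	pw2-01	pw2-02	pw2-03	pw2-04	pw2-05	pw2-06	pw2-07	pw2-08	pw2-09	pw2-10	pw2-11	pw2-12	pw2-13	pw2-14	pw2-15	pw2-16
pathway3	synthetic metabolic pathway (names match the timepoints preset)	pw3-01	pw3-02	pw3-03	pw3-04	pw3-05	pw3-06	pw3-07	pw3-08	pw3-09	pw3-10	pw3-11	pw3-12	pw3-13	pw3-14	pw3-15	pw3-16
pathway4	synthetic metabolic pathway (names match the timepoints preset)	pw4-01	pw4-02	pw4-03	pw4-04	pw4-05	pw4-06	pw4-07	pw4-08	pw4-09	pw4-10	pw4-11	pw4-12	pw4-13	pw4-14	pw4-15	pw4-16
pathway5	synthetic metabolic pathway (names match the timepoints preset)	pw5-01	pw5-02	pw5-03	pw5-04	pw5-05	pw5-06	pw5-07	pw5-08	pw5-09	pw5-10	pw5-11	pw5-12	pw5-13	pw5-14	pw5-15	pw5-16
pathway6	synthetic metabolic pathway (names match the timepoints preset)	pw6-01	pw6-02	pw6-03	pw6-04	pw6-05	pw6-06	pw6-07	pw6-08	pw6-09	pw6-10	pw6-11	pw6-12	pw6-13	pw6-14	pw6-15	pw6-16
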